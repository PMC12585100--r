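---
title: "Methods: whole-brain modelling of NREM sleep functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain modelling of NREM sleep functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sleepwc` implements a complete in-silico pipeline for studying how the
wake-promoting neuromodulators acetylcholine (ACh) and noradrenaline (NA)
reshape BOLD functional connectivity (FC) across wakefulness (W) and the
NREM sleep stages N1–N3. The pipeline has five layers: a Wilson–Cowan
neural-mass network with homeostatic inhibitory plasticity; a
Balloon–Windkessel hemodynamic stage with band-pass filtering and TR
resampling; neuromodulatory parameter fields built from regional modulation
maps; FC fitting by a `(δG, δσ)` grid sweep under the euccorrelation
semi-metric; and Hierarchical Modular Analysis (HMA) of integration and
segregation, plus the statistical toolkit used to compare stages and
modelling modalities. A synthetic-data generator supplies connectomes,
maps, and multi-subject stage datasets with known ground truth so the whole
pipeline is testable without any external data.

# The neural mass model

Each brain region holds an excitatory population `E_i` and an inhibitory
population `I_i`:

    tau_E dE_i/dt = -E_i + (1 - r_E E_i) S_E(a_EE E_i - a_i^IE I_i
                      + G_i * sum_j C_ji E_j + P + D eps_i)
    tau_I dI_i/dt = -I_i + (1 - r_I I_i) S_I(a_EI E_i)
    tau_ip da_i^IE/dt = I_i (E_i - rho_E)

with the logistic transfer `S(x) = 1 / (1 + exp(-(x - mu)/sigma))`. The
defaults are `r_E = r_I = 0.5`, `tau_E = 0.01` s, `tau_I = 0.02` s,
`a_EE = 3.5`, `a_EI = 3.75`, `P = 0.4`, `D = 0.002`, `rho_E = 0.18`,
`mu = 1`, `sigma_I = 4`. The third equation is the homeostatic inhibitory
plasticity rule: the inhibitory-to-excitatory weight grows whenever
excitatory activity exceeds the set point `rho_E`, so each region's
time-averaged activity is driven to `rho_E` regardless of its inputs. This
is the property that makes the model robust under the large parameter
excursions of a sweep, and it is the package's primary acceptance check
(mean `E_i` within 0.02 of 0.18 over the analysis window).

Integration is plain Euler at `dt = 1e-4` s: a 400 s transient with fast
plasticity (`tau_ip = 0.05` s) is discarded, then 600 s with
`tau_ip = 2` s form the analysis window. With the shallow excitatory
transfer of the fitted wake state, the homeostatic loop relaxes with an
effective time constant of roughly 20 s under fast plasticity (the loop
gain is the product of plasticity speed and the small sensitivity
`dE/da^IE`), so the 400 s transient leaves the equilibrium residual far
below measurement precision.

## Numerical and design choices

* **Coupling placement.** The long-range term is `G_i * sum_j C_ji E_j`.
  A global coupling that is swept and regionally modulated must multiply
  the connectome input; any other placement makes the sweep a no-op.
* **Noise convention.** The noise is specified as zero-centred white noise
  with scale `D` entering the excitatory sigmoid argument. White noise in
  a differential equation is delta-correlated, so its Euler discretization
  is `D * eps_k / sqrt(dt)` with `eps_k ~ N(0,1)` per region per step; this
  is the default (`noise_convention = "white"`) and is step-size
  consistent. The literal reading — a bounded `D * eps_k` fluctuation per
  step — is available as `"per_step"`, but its integrated effect scales as
  `sqrt(dt)` and vanishes under step refinement; at `dt = 1e-4` it leaves
  the trajectories effectively deterministic, which would make every
  simulation seed equivalent and FC estimation degenerate. The white-noise
  reading is the only one under which seed ensembles (and the observed
  spread of fit values across seeds) are meaningful.
* **Sigmoid slope convention.** `sigma` divides in the exponent, exactly as
  written above, for both populations; the NA offset `δσ` therefore adds to
  `sigma_E` directly. One consequence worth knowing: with a larger
  `sigma_E` the transfer is shallower, so the wake operating point
  (`sigma_E = 7.7`) sits in a stable, noise-driven fluctuation regime
  rather than a limit-cycle regime, and FC is carried by correlated
  noise propagation through the connectome.
* **Initial conditions** (`E = I = 0.1`, `a^IE = 1`) are irrelevant to the
  analysis window: the fast-plasticity transient erases them, which the
  suite verifies by integrating from displaced initial states.
* **Nonnegativity.** `a^IE` is clipped at zero: a negative
  inhibitory-to-excitatory weight has no biological meaning and the
  plasticity rule alone does not forbid it.
* **State recording.** The trajectory is recorded every 10 steps (1 ms),
  which is also the hemodynamic integration step, reconciling the two
  printed step sizes (1e-4 s neural, 1e-3 s hemodynamic).

# Hemodynamics

The Balloon–Windkessel stage maps excitatory activity to a BOLD readout
through vasodilatory signal `s`, inflow `f`, venous volume `v` and
deoxyhemoglobin `q`, with `tau_s = 0.65`, `tau_f = 0.41`,
`tau_v = tau_q = 0.98` s, stiffness exponent `kappa = 0.32` (outflow
`v^(1/kappa)`, the standard Grubb form), `E_0 = 0.4`, `V_0 = 0.04`,
`k_1 = 2.77`, `k_2 = 0.2`, `k_3 = 0.5`, integrated with Euler at 1 ms from
rest (`s = 0, f = v = q = 1`). Rest is an exact fixed point with zero
BOLD, and constant drives converge to steady states that the test suite
checks against an independently solved algebraic fixed point at 1e-6.

BOLD post-processing band-passes to 0.01–0.1 Hz with a 2nd-order Bessel
design and resamples to `TR = 2` s. Numerical choices:

* The Bessel band-pass is designed from the analytic second-order Bessel
  low-pass prototype (denominator `s^2 + 3s + 3`, rescaled so its −3 dB
  point is the corner), band-transformed and bilinear-digitized.
* **Order of filtering and decimation.** By default the series is
  decimated to TR first and the filter applied at the `1/TR` rate. A
  band-pass with corners at 1e-5–1e-4 of the Nyquist frequency (which is
  what 0.01 Hz means at the native 1 kHz rate) is numerically unusable in
  transfer-function form; after decimation the corners sit at 4–40% of
  Nyquist, where the design is well-conditioned. The BOLD signal is
  hemodynamically smooth far below the post-decimation Nyquist rate, so no
  separate anti-alias stage is needed. `filter_first = TRUE` restores the
  filter-then-decimate order for inputs whose native rate is moderate.
* Filtering is zero-phase (forward–backward) by default because FC is
  phase-sensitive; a forward-only option exists.
* Each series is demeaned before filtering: zero-phase filtering of a
  signal whose DC offset dwarfs its fluctuations otherwise injects edge
  transients that are common to all regions and would masquerade as
  connectivity.
* In the combined `simulate_bold()` path the hemodynamic state is
  integrated warm through the neural transient, so the analysis window
  starts with the vasculature equilibrated instead of relaxing from rest
  inside the window.

# Neuromodulation

Regional parameter fields follow

    G_i       = G + δG * ACh_i
    sigma_E_i = sigma + δσ * NA_i

where `ACh_i` and `NA_i` are positive regional maps normalized to mean 1
(so a map-weighted offset equals the homogeneous offset on average). ACh
tone is mapped inversely onto the global coupling — the fitted axis flips,
with lower ACh appearing as higher `G` — and NA tone maps directly onto
the excitatory slope. For projection maps whose thalamic entries dwarf the
cortex, `normalize_map(deescalate_thalamus = TRUE)` clips thalamic values
to the non-thalamic maximum before normalization. A nonpositive regional
slope or negative coupling is a hard error — the transfer function is
undefined there — and sweeps record such grid points as infeasible
(`Inf`) rather than clamping silently.

Shuffled-map surrogates permute the homotopic-pair values once and apply
the same permutation to both hemispheres. This is the only reading of a
hemisphere-symmetric shuffle that preserves homotopic correspondence, and
with it the surrogate's correlation against a homotopically symmetric
connectome is structurally preserved; per-hemisphere means and the value
multiset are conserved exactly. Independent per-hemisphere permutation is
available behind `joint = FALSE`.

# Homotopic connectome enhancement

Diffusion imaging underestimates interhemispheric connections, so before
fitting, homotopic structural entries can be adapted by

    SC[i, partner(i)] <- SC[i, partner(i)] + eta * (FC_emp - FC_sim)

for 60 epochs, with the simulated FC averaged over 20 seeds per epoch,
updates restricted to homotopic entries, symmetric, and floored at zero.
The forward engine is pluggable; the package default is its own
Wilson–Cowan + hemodynamics model. The learning rate is not part of the
printed protocol; the default `eta = 0.05` carries a divergence guard that
halves `eta` whenever the homotopic error grows two epochs in a row.

# Fit metric and parameter sweeps

FC matrices are compared on their strict lower triangles through the
euccorrelation semi-metric

    euccorr(v1, v2) = euclidean(v1, v2) / |pearson(v1, v2)|

which penalizes both amplitude mismatch (numerator) and pattern mismatch
(denominator); it is zero only for identical vectors and never smaller
than the Euclidean distance. A correlation of zero maps to `Inf` rather
than an error so that sweep argmins simply never select such points.

`run_sweep()` evaluates the forward model over an equidistant, inclusive
`(δG, δσ)` grid (50 × 50 over `[-0.5, 0.5] × [-1, 1]` at full scale; the
inclusive construction makes the conventionally reported optima exact grid
values). Design choices:

* The optimum is the argmin of the **seed-mean** fit (median optional).
  The per-seed fits at that optimum provide the distributions used for
  modality comparisons.
* Seed `s` at every grid point reuses the same base seed + offset: common
  random numbers across the grid remove seed-to-seed jitter from the
  landscape comparison, and make a homogeneous sweep bitwise identical to
  a sweep with unit maps.
* Exact ties break toward the smallest `|δG|`, then smallest `|δσ|`, then
  the earlier grid index — fully deterministic.
* The wake baseline `(G, sigma)` is fitted first as an absolute sweep
  (defaults bracket `G in [0, 0.3]`, `sigma in [1, 12]`); stage optima are
  expressed as offsets from it.

Modality comparisons use Cohen's d between per-seed optimal fits
(map − homogeneous and map − shuffle; negative d means the map modality
fits better) and between the per-seed correlations of simulated and
empirical nodal integration/segregation profiles.

# Hierarchical Modular Analysis

HMA decomposes a symmetric FC matrix into eigenmodes (eigenvalues
descending) and builds nested sign partitions: level 1 is the whole
network; level `i` splits each level-`(i-1)` module by the sign of
eigenvector `u_i` inside it. With module count `M_i`, sizes `m_j`, and the
size-heterogeneity correction `p_i = sum_j |m_j - N/M_i| / N`, each level
contributes `H_i = Lambda_i^2 M_i (1 - p_i) / N`; global integration is
`H_in = H_1/N`, global segregation `H_se = sum_{i>=2} H_i / N`, and nodal
components weight `H_i` by the squared eigenvector entries. Conventions
the source formulation leaves open, fixed here:

* A sign-uniform module does not split and is carried forward, so
  `M_i <= min(2^(i-1), N)` rather than exactly `2^(i-1)` (forcing the
  power of two is impossible for sign-uniform modules).
* Zero eigenvector entries side with the nonnegative-sign submodule.
* Within a numerically degenerate eigenvalue block, eigenvectors are
  ordered by the row of their largest-magnitude entry and sign-fixed so
  that entry is positive; results inside such a block are basis-dependent
  and should not be over-interpreted.
* The segregation sum runs over all levels up to `N`, with no truncation.
* For correlation (positive semidefinite) inputs all `H_i` are
  nonnegative, and the nodal components satisfy
  `sum_j (H_in_j + H_se_j) = N (H_in + H_se)` to 1e-8 — both are enforced
  by tests.

# Statistics

Cohen's d uses the pooled-SD (classical) form, not the small-sample
corrected variant, with interpretation bins at |d| thresholds
0.2 / 0.5 / 0.8 / 1.2 / 2 (boundary values go to the higher bin —
arbitrary, documented). Stage-versus-wake comparisons of per-area
quantities (nodal strength, nucleus FC) are paired by brain area, matching
panels whose points are areas averaged across individuals. Families of
paired t-tests are corrected with Benjamini–Hochberg step-up via
`p.adjust`. Repeated-measures correlation is implemented in its ANCOVA
form (subject-specific intercepts, shared slope) with
`dof = N_obs - N_subjects - 1`; subjects with constant predictor values
are dropped with a warning.

# The synthetic-data generator

The generator emulates the study's inputs, not their biophysics:

* **Connectomes** are built from mirrored modular blocks with a sparse
  background, plus uniform homotopic connections, so the hemispheric
  symmetry that map shuffling relies on holds by construction. Weights
  are in arbitrary units; the generator fixes the unit by scaling the
  matrix so the linearized coupling gain at the wake operating point
  (`G = 0.14`, `sigma_E = 7.7`, activity at `rho_E`) equals 0.5. Below 1
  the network is stable but susceptible — long-range input visibly shapes
  correlations — which is the regime in which whole-brain models are known
  to reproduce empirical FC. The value 0.5 also leaves headroom for the
  sweep: the fitted stage offsets reach `δG = 0.2` with map values near 2,
  i.e. regional couplings of up to about four times the wake baseline, and
  those excursions must stay subcritical (gain below 1) for the simulated
  FC to remain structured rather than saturating into global synchrony, as
  empirical stage FC does.
* **Maps** are lognormal (positive, right-skewed, as transporter and
  projection densities are), hemisphere-symmetric, mean-normalized, with a
  controllable spatial correlation between the ACh-like and NA-like map.
* **Stage datasets** run the full forward model per subject and stage at
  stage-specific `(δG, δσ)` with Gaussian per-subject jitter; the exact
  generating values are returned as ground truth for recovery testing.
  The default stage offsets are the fitted heterogeneous optima of the
  wake-to-N3 protocol: `δG = 0, 0.18, 0.20, 0.02` and
  `δσ = -0.02, -0.02, -0.04, -0.12` for W, N1, N2, N3, around the wake
  baseline `(G, sigma) = (0.14, 7.7)`.
* **Nucleus signals** (BF- and LC-like) are map-weighted averages of the
  regional series plus white noise, mimicking how a small nucleus's BOLD
  trace reflects its projection field.

What passing synthetic tests do and do not show: they demonstrate that the
pipeline is internally consistent — parameters that generated the data are
recovered by the sweep, true maps beat shuffled maps when heterogeneity is
real, integration/segregation track coupling and slope as designed. They
do not show that real NREM data satisfy these assumptions: empirical BOLD
has head motion, physiological nuisance structure, non-stationarity within
stages, and hemodynamic variability that the generator deliberately omits.

# Problem sizes

Production settings follow the full protocol (90 regions, `dt = 1e-4`,
400 s + 600 s, 50 × 50 grids, 50 seeds); these are cluster-scale. The
package's desk profile, used throughout the test suite and chosen as a
deliberate package default for interactive work, is: `dt = 1e-3` with a
120 s transient and 180 s window (`desk_sim_config()`); 8–24 regions;
5 × 5 offset grids with 3 seeds per point for recovery checks (10
generator replicates, success within one grid step in at least 8); and a
12-seed refit at each modality optimum for effect-size comparisons. At
`dt = 1e-3` the homeostatic mean and FC behaviour agree with the fine-step
protocol to well within the tolerances tested; the full-scale default
configuration is exercised end to end by the homeostasis acceptance check
and the acceptance script.

# Known limitations

* The model omits GABAergic and serotonergic modulation, thalamocortical
  loop detail, and any electrophysiological observables (spindles, slow
  waves); REM sleep is out of scope.
* All regions share one hemodynamic response; subject-level hemodynamic
  variability is not modelled.
* The empirical-data path assumes already-parcellated time series; no
  imaging preprocessing is provided.
* Whether deposited empirical series are already confound-regressed or
  band-filtered cannot be assumed; the loaders leave series untouched and
  the PPN-regression step is composed explicitly in the workflow.
* Map heterogeneity enters as a single signed offset per neuromodulator:
  all regions move in the same direction, so regionally antagonistic
  neuromodulation cannot be expressed.
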