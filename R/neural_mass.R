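#' Wilson-Cowan simulation configuration
#'
#' All parameters of the neural mass network with homeostatic inhibitory
#' plasticity. Defaults are the standard whole-brain protocol: a 400 s
#' transient integrated with fast plasticity (`tau_ip_transient = 0.05` s),
#' discarded, followed by a 600 s analysis window with `tau_ip_main = 2` s,
#' Euler step `dt = 1e-4` s, and state recorded every `stride` steps (1 ms).
#'
#' `G` and `sigma_E` may be scalars (homogeneous) or per-region vectors as
#' produced by [apply_modulation()]. The homeostatic rule drives each
#' excitatory population to oscillate around `rho_E`.
#'
#' @param r_E,r_I self-response constants (0.5).
#' @param tau_E,tau_I excitatory/inhibitory time constants, seconds.
#' @param a_EE,a_EI intra-node coupling constants.
#' @param P external input to the excitatory population.
#' @param D noise scaling factor; a fresh standard-normal draw per region
#'   per Euler step enters the excitatory sigmoid argument.
#' @param rho_E homeostatic target for excitatory activity.
#' @param mu sigmoid position.
#' @param sigma_I inhibitory sigmoid slope (held fixed).
#' @param G global coupling, scalar or per-region vector.
#' @param sigma_E excitatory sigmoid slope, scalar or per-region vector.
#'   Defaults to the fitted wake operating point.
#' @param tau_ip_transient,tau_ip_main plasticity time constants, seconds.
#' @param dt Euler step, seconds.
#' @param t_transient,t_main transient and analysis durations, seconds.
#' @param stride record every `stride` steps (default gives 1 ms sampling).
#' @param noise_convention `"white"` (default) treats the noise as
#'   delta-correlated white noise of amplitude `D`, discretized as
#'   `D * eps / sqrt(dt)` so the integrated dynamics are step-size
#'   consistent; `"per_step"` uses the literal bounded per-step fluctuation
#'   `D * eps`, whose effect vanishes as `dt` shrinks (kept for
#'   comparability).
#' @param init_E,init_I,init_a_IE initial conditions (the fast-plasticity
#'   transient makes the attractor insensitive to these).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(r_E = 0.5, r_I = 0.5, tau_E = 0.01, tau_I = 0.02,
                       a_EE = 3.5, a_EI = 3.75, P = 0.4, D = 0.002,
                       rho_E = 0.18, mu = 1, sigma_I = 4,
                       G = 0.14, sigma_E = 7.7,
                       tau_ip_transient = 0.05, tau_ip_main = 2,
                       dt = 1e-4, t_transient = 400, t_main = 600,
                       stride = 10, noise_convention = c("white", "per_step"),
                       init_E = 0.1, init_I = 0.1, init_a_IE = 1) {
  noise_convention <- match.arg(noise_convention)
  cfg <- list(r_E = r_E, r_I = r_I, tau_E = tau_E, tau_I = tau_I,
              a_EE = a_EE, a_EI = a_EI, P = P, D = D, rho_E = rho_E,
              mu = mu, sigma_I = sigma_I, G = G, sigma_E = sigma_E,
              tau_ip_transient = tau_ip_transient, tau_ip_main = tau_ip_main,
              dt = dt, t_transient = t_transient, t_main = t_main,
              stride = as.integer(stride),
              noise_convention = noise_convention,
              init_E = init_E, init_I = init_I, init_a_IE = init_a_IE)
  for (f in c("tau_E", "tau_I", "tau_ip_transient", "tau_ip_main", "dt",
              "t_main"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (t_transient < 0) stop("t_transient must be nonnegative")
  if (any(sigma_E <= 0)) stop("sigma_E must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale simulation profile
#'
#' A reduced profile for interactive work and tests: coarser Euler step
#' (`dt = 1e-3` s, state recorded every step so the hemodynamic stage still
#' sees a 1 ms series), a 120 s transient (the homeostatic loop relaxes
#' with an effective time constant near 20 s under fast plasticity, so this
#' suffices for convergence) and a 180 s analysis window.
#' Dynamics agree closely with the fine-step protocol (see the methods
#' vignette); use [sim_config()] defaults for production runs.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
desk_sim_config <- function(...) {
  args <- list(dt = 1e-3, stride = 1L, t_transient = 120, t_main = 180)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Sigmoid activation function
#'
#' `S(x) = 1 / (1 + exp(-(x - mu) / sigma))`, the input-output function of
#' each population; `sigma` is the slope parameter modulated by noradrenaline
#' in the excitatory populations.
#'
#' @param x input (scalar or vector).
#' @param mu position parameter.
#' @param sigma slope parameter, must be positive.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x, mu = 1, sigma = 4) {
  if (any(sigma <= 0)) stop("sigmoid slope sigma must be positive")
  1 / (1 + exp(-(x - mu) / sigma))
}

#' Wilson-Cowan derivatives
#'
#' Right-hand side of the coupled excitatory/inhibitory equations with the
#' homeostatic plasticity rule, for one network state. Mainly useful for
#' fixed-point analysis and testing; [simulate_wc()] integrates in compiled
#' code.
#'
#' @param E,I,a_IE numeric state vectors of length N.
#' @param config a [sim_config()].
#' @param connectome a [connectome()] or bare weight matrix.
#' @param noise per-region noise draw (enters as `D * noise` inside the
#'   excitatory sigmoid argument); defaults to zero.
#' @param tau_ip plasticity time constant to use (defaults to the main-window
#'   value).
#' @return List with `dE`, `dI`, `da_IE`.
#' @export
wc_derivatives <- function(E, I, a_IE, config, connectome,
                           noise = 0, tau_ip = config$tau_ip_main) {
  C <- conn_weights(connectome)
  n <- length(E)
  stopifnot(length(I) == n, length(a_IE) == n, nrow(C) == n)
  G <- rep_len(config$G, n)
  sE <- rep_len(config$sigma_E, n)
  noise <- rep_len(noise, n)
  coup <- as.vector(crossprod(C, E))  # sum_j C_ji E_j
  argE <- config$a_EE * E - a_IE * I + G * coup + config$P + config$D * noise
  dE <- (-E + (1 - config$r_E * E) * sigmoid(argE, config$mu, sE)) / config$tau_E
  dI <- (-I + (1 - config$r_I * I) * sigmoid(config$a_EI * E, config$mu,
                                             config$sigma_I)) / config$tau_I
  da <- I * (E - config$rho_E) / tau_ip
  list(dE = dE, dI = dI, da_IE = da)
}

cfg_vectors <- function(config, n) {
  list(G = rep_len(as.numeric(config$G), n),
       sigma_E = rep_len(as.numeric(config$sigma_E), n))
}

#' Simulate the Wilson-Cowan network
#'
#' Euler integration at `config$dt` with a fresh standard-normal draw per
#' region per step. The transient (`t_transient` s, fast plasticity) is
#' discarded; the analysis window (`t_main` s, slow plasticity) is returned,
#' sampled every `stride` steps. Deterministic for a given seed.
#'
#' @param connectome a [connectome()] or weight matrix.
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @param record_I,record_a also record the inhibitory activity / plasticity
#'   weight paths.
#' @return Object of class `wc_trajectory`: `E` (and optionally `I`, `a_IE`)
#'   as region-by-time matrices, `sample_interval` (s), `e_mean` (per-node
#'   time-mean of E over the full analysis window), `seed`.
#' @export
simulate_wc <- function(connectome, config = sim_config(), seed = 1,
                        record_I = FALSE, record_a = FALSE) {
  C <- conn_weights(connectome)
  vec <- cfg_vectors(config, nrow(C))
  set.seed(seed)
  out <- wc_sim_cpp(C, vec$G, vec$sigma_E, unclass(config), record_I, record_a)
  out$seed <- seed
  class(out) <- "wc_trajectory"
  out
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat("Wilson-Cowan trajectory:", nrow(x$E), "regions x", ncol(x$E),
      "samples at", x$sample_interval, "s (seed", x$seed, ")\n")
  cat("  mean excitatory activity:", round(mean(x$e_mean), 4), "\n")
  invisible(x)
}
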