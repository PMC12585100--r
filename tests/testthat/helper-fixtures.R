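# Shared fixtures: all built in code, tiny enough for second-scale tests.

# fast simulation profile for contract tests (not for quantitative checks)
tiny_config <- function(...) {
  # window must exceed three time constants of the 0.01 Hz band edge
  desk_sim_config(t_transient = 30, t_main = 60, ...)
}

# small connectome reused across tests
tiny_connectome <- function(n = 8, seed = 5) {
  make_connectome(n, n_modules = 2, density = 0.5, seed = seed)
}

# deterministic symmetric correlation-like matrix (PSD)
random_corr <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3 * n), n, 3 * n)
  stats::cov2cor(tcrossprod(x) / (3 * n))
}

# independent single-node equilibrium oracle (G = 0, D = 0):
# da/dt = 0 forces E = rho_E; I from its own fixed-point equation via a
# root finder; a_IE from inverting the excitatory sigmoid argument.
single_node_oracle <- function(cfg) {
  S_I <- function(x) 1 / (1 + exp(-(x - cfg$mu) / cfg$sigma_I))
  E <- cfg$rho_E
  I <- uniroot(function(I) I - (1 - cfg$r_I * I) * S_I(cfg$a_EI * E),
               c(0, 1), tol = 1e-14)$root
  s_target <- E / (1 - cfg$r_E * E)
  arg <- cfg$mu + cfg$sigma_E * log(s_target / (1 - s_target))
  a <- (cfg$a_EE * E + cfg$P - arg) / I
  c(E = E, I = I, a_IE = a)
}

# independent Balloon-Windkessel steady-state oracle for constant drive u:
# df/dt = 0 => s = 0; ds/dt = 0 => f = 1 + tau_f * u; v from a root finder
# on the volume equation; q from the deoxyhemoglobin balance.
bw_steady_oracle <- function(u, h) {
  f <- 1 + h$tau_f * u
  v <- uniroot(function(v) f - v^(1 / h$kappa), c(1e-6, 100), tol = 1e-14)$root
  q <- f * (1 - (1 - h$E_0)^(1 / f)) / h$E_0 * v / v^(1 / h$kappa)
  B <- h$V_0 * (h$k_1 * (1 - q) + h$k_2 * (1 - q / v) + h$k_3 * (1 - v))
  c(s = 0, f = f, v = v, q = q, B = B)
}
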