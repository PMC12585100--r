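#' Synthetic modular, homotopically symmetric connectome
#'
#' Builds a weight matrix with mirrored module structure across hemispheres:
#' the left-hemisphere block carries `n_modules` modules of lognormal
#' within-module weights over a sparse uniform background, the right block
#' is its mirror image, cross-hemisphere background is mirrored likewise,
#' and every homotopic pair `(i, partner(i))` is connected with weight
#' `homotopic_weight`.
#'
#' Connectome weights are in arbitrary units; the generator fixes them by
#' scaling the matrix so that the linearized coupling gain at the wake
#' operating point (`reference` coupling and slope, homeostatic set point
#' activity) equals `spectral_gain`. Below 1 the network is stable but
#' susceptible: long-range input visibly shapes correlations, which is the
#' regime where whole-brain models reproduce empirical FC, and it makes the
#' printed wake coupling a meaningful operating point for synthetic data.
#'
#' @param n_regions even number of regions.
#' @param n_modules modules per hemisphere (at most `n_regions / 2`).
#' @param homotopic_weight weight of homotopic connections, pre-scaling.
#' @param density probability that a non-homotopic pair is connected.
#' @param seed integer RNG seed.
#' @param spectral_gain target linearized coupling gain
#'   `lambda_max(C) * G_ref * S'_E` at the reference operating point.
#' @param reference `c(G, sigma)` operating point used for the scaling.
#' @return A [connectome()].
#' @export
make_connectome <- function(n_regions = 90, n_modules = 3,
                            homotopic_weight = 1, density = 0.3, seed = 1,
                            spectral_gain = 0.5,
                            reference = c(G = 0.14, sigma = 7.7)) {
  if (n_regions < 4 || n_regions %% 2 != 0)
    stop("n_regions must be an even integer >= 4")
  half <- n_regions / 2L
  if (n_modules < 1 || n_modules > half)
    stop("n_modules must be between 1 and n_regions / 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (homotopic_weight < 0) stop("homotopic_weight must be nonnegative")
  set.seed(seed)
  module <- rep(seq_len(n_modules), length.out = half)[order(runif(half))]
  # left-left block: symmetric, sparse background + strong within-module
  L <- matrix(0, half, half)
  X <- matrix(0, half, half)  # left-right cross block (pair coordinates)
  for (i in seq_len(half - 1)) {
    for (j in (i + 1):half) {
      if (runif(1) < density) {
        w <- if (module[i] == module[j]) exp(rnorm(1, 0, 0.5)) else
          0.3 * exp(rnorm(1, 0, 0.5))
        L[i, j] <- L[j, i] <- w
      }
      if (runif(1) < density) {
        w <- if (module[i] == module[j]) 0.5 * exp(rnorm(1, 0, 0.5)) else
          0.15 * exp(rnorm(1, 0, 0.5))
        X[i, j] <- X[j, i] <- w
      }
    }
  }
  diag(X) <- homotopic_weight
  W <- rbind(cbind(L, X), cbind(t(X), L))  # right block mirrors the left
  # scale to the susceptible regime at the reference operating point
  # (spectral_gain = NULL keeps the raw weights)
  if (!is.null(spectral_gain)) {
    cfg0 <- sim_config(G = reference[1], sigma_E = reference[2])
    s_op <- cfg0$rho_E / (1 - cfg0$r_E * cfg0$rho_E)
    slope <- s_op * (1 - s_op) / reference[2]
    lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
    if (lam > 0) W <- W * spectral_gain / (reference[1] * slope * lam)
  }
  connectome(W, make_region_table(n_regions))
}

#' Synthetic ACh / NA modulation maps
#'
#' Draws two lognormal, hemisphere-symmetric, mean-1 regional maps whose
#' Pearson correlation approximates `spatial_correlation`. Values are drawn
#' per homotopic pair on a correlated bivariate normal, exponentiated,
#' mirrored to both hemispheres, and mean-normalized; draws are repeated
#' (fresh randomness, same stream) until the realized correlation is within
#' 0.15 of the request.
#'
#' @param regions region table.
#' @param spatial_correlation target correlation in `[-1, 1]`.
#' @param seed integer RNG seed.
#' @param sdlog lognormal shape (spread of regional receptivity).
#' @param max_attempts attempts before a convergence error.
#' @return List with elements `ach`, `na`, both normalized [modulation_map()]s.
#' @export
make_maps <- function(regions, spatial_correlation = 0.3, seed = 1,
                      sdlog = 0.4, max_attempts = 100) {
  validate_region_table(regions)
  if (abs(spatial_correlation) > 1) stop("spatial_correlation must be in [-1, 1]")
  n <- nrow(regions)
  left <- which(regions$hemisphere == "left")
  partner <- as.integer(regions$homotopic_partner)
  set.seed(seed)
  rho <- spatial_correlation
  for (attempt in seq_len(max_attempts)) {
    z1 <- rnorm(length(left))
    z2 <- if (abs(rho) == 1) sign(rho) * z1 else
      rho * z1 + sqrt(1 - rho^2) * rnorm(length(left))
    a <- numeric(n); b <- numeric(n)
    a[left] <- exp(sdlog * z1); a[partner[left]] <- a[left]
    b[left] <- exp(sdlog * z2); b[partner[left]] <- b[left]
    if (rho == 1) b <- a  # exact limit case
    a <- a / mean(a); b <- b / mean(b)
    ok <- if (abs(rho) == 1) TRUE else abs(cor(a, b) - rho) <= 0.15
    if (ok)
      return(list(ach = modulation_map(a, "ACh", normalized = TRUE),
                  na = modulation_map(b, "NA", normalized = TRUE)))
  }
  stop("could not reach requested spatial correlation within ",
       max_attempts, " attempts")
}

#' Simulate a multi-subject, multi-stage BOLD dataset
#'
#' Runs the forward model (neural mass + hemodynamics + post-processing) for
#' every subject and stage at stage-specific `(dG, dsigma)` offsets with
#' per-subject parameter jitter, and records the exact generating parameters
#' as ground truth. Default stage offsets are the fitted heterogeneous
#' optima of the wake-to-N3 study protocol.
#'
#' @param connectome a [connectome()].
#' @param ach,na normalized [modulation_map()]s (or `NULL` for homogeneous
#'   generation).
#' @param stage_params named list `stage -> c(dG, dsigma)` covering all four
#'   stages.
#' @param n_subjects number of subjects.
#' @param subject_noise_sd standard deviation of the per-subject jitter added
#'   to both offsets.
#' @param baseline `c(G, sigma)` homogeneous baseline.
#' @param config a [sim_config()] (duration, dt etc.); defaults to the desk
#'   profile.
#' @param hemo a [hemo_config()].
#' @param TR,band BOLD sampling interval and band-pass corners.
#' @param seed integer RNG seed.
#' @return List with `datasets` (list of [stage_dataset()]) and
#'   `ground_truth` (stage parameters, subject jitters, baseline, maps, seed).
#' @export
simulate_stage_dataset <- function(connectome, ach = NULL, na = NULL,
                                   stage_params = list(
                                     W = c(0.00, -0.02), N1 = c(0.18, -0.02),
                                     N2 = c(0.20, -0.04), N3 = c(0.02, -0.12)),
                                   n_subjects = 5, subject_noise_sd = 0.01,
                                   baseline = c(G = 0.14, sigma = 7.7),
                                   config = desk_sim_config(),
                                   hemo = hemo_config(), TR = 2,
                                   band = c(0.01, 0.1), seed = 1) {
  if (!all(STAGES %in% names(stage_params)))
    stop("stage_params must cover W, N1, N2, N3")
  n <- nrow(conn_weights(connectome))
  set.seed(seed)
  jitter <- matrix(rnorm(2 * n_subjects, 0, subject_noise_sd), ncol = 2)
  sim_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                 n_subjects * length(STAGES)),
                      nrow = n_subjects)
  datasets <- list()
  truth_pars <- list()
  for (si in seq_len(n_subjects)) {
    sid <- sprintf("sub%02d", si)
    for (ki in seq_along(STAGES)) {
      stg <- STAGES[ki]
      dG <- stage_params[[stg]][1] + jitter[si, 1]
      ds <- stage_params[[stg]][2] + jitter[si, 2]
      mod <- apply_modulation(baseline[1], baseline[2], dG, ds, ach, na, n = n)
      cfg <- config
      cfg$G <- mod$G_i
      cfg$sigma_E <- mod$sigma_E_i
      sim <- simulate_bold(connectome, cfg, hemo, seed = sim_seeds[si, ki],
                           TR = TR, band = band)
      datasets[[length(datasets) + 1]] <-
        stage_dataset(sid, stg, sim$bold$values, TR = TR)
      truth_pars[[paste(sid, stg, sep = "_")]] <- c(dG = dG, dsigma = ds)
    }
  }
  ground_truth <- list(stage_params = stage_params,
                       subject_jitter = jitter,
                       subject_params = truth_pars,
                       baseline = baseline,
                       ach = ach, na = na, seed = seed,
                       sim_seeds = sim_seeds)
  list(datasets = datasets, ground_truth = ground_truth)
}

#' Nucleus-like signal from regional series
#'
#' Map-weighted average of the regional signals plus white noise, emulating
#' the BOLD time course of a neuromodulatory nucleus (BF or LC) whose
#' projections follow the map.
#'
#' @param region_series region-by-time matrix.
#' @param map a [modulation_map()] or weight vector matching the region count.
#' @param noise_sd standard deviation of the added white noise.
#' @param seed integer RNG seed.
#' @return Numeric vector (1 x time).
#' @export
make_nucleus_series <- function(region_series, map, noise_sd = 0, seed = 1) {
  region_series <- as.matrix(region_series)
  w <- map_values(map)
  if (length(w) != nrow(region_series))
    stop("map length (", length(w), ") does not match region count (",
         nrow(region_series), ")")
  set.seed(seed)
  sig <- as.numeric(crossprod(region_series, w / sum(w)))
  sig + rnorm(length(sig), 0, noise_sd)
}
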