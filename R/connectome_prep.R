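#' Iterative homotopic connection enhancement
#'
#' Diffusion imaging underestimates interhemispheric connectivity; this
#' routine strengthens homotopic structural connections so that simulated FC
#' matches empirical FC on those entries. At each epoch the forward model
#' produces a simulated FC (averaged over `seeds_per_epoch` seeds) and only
#' homotopic entries are updated by
#' `SC[i, partner(i)] <- SC[i, partner(i)] + eta * (FC_emp - FC_sim)`,
#' symmetrically, floored at zero. All non-homotopic entries are returned
#' bit-identical to the input. If the homotopic error grows two epochs in a
#' row, `eta` is halved (divergence guard).
#'
#' @param sc a [connectome()].
#' @param fc_target empirical FC matrix.
#' @param forward_model `function(connectome, seeds)` returning a simulated
#'   FC matrix averaged over the integer seed vector `seeds`; see
#'   [wc_forward_model()].
#' @param eta learning rate.
#' @param epochs number of update epochs.
#' @param seeds_per_epoch seeds averaged per epoch.
#' @param seed base seed; epoch `t` uses seeds
#'   `seed + (t - 1) * seeds_per_epoch + 0:(seeds_per_epoch - 1)`.
#' @param verbose print the homotopic error per epoch.
#' @return A [connectome()] with updated homotopic weights; the per-epoch
#'   mean absolute homotopic error is attached as attribute `"error"`.
#' @export
enhance_homotopic <- function(sc, fc_target, forward_model, eta = 0.05,
                              epochs = 60, seeds_per_epoch = 20, seed = 1,
                              verbose = FALSE) {
  stopifnot(inherits(sc, "connectome"))
  fc_target <- check_fc(fc_target)
  if (any(abs(fc_target) > 1 + 1e-8)) stop("fc_target entries must be in [-1, 1]")
  W <- sc$weights
  n <- nrow(W)
  partner <- as.integer(sc$regions$homotopic_partner)
  hom <- cbind(seq_len(n), partner)
  err <- numeric(epochs)
  grew <- 0L
  for (t in seq_len(epochs)) {
    seeds <- seed + (t - 1L) * seeds_per_epoch + seq_len(seeds_per_epoch) - 1L
    fc_sim <- tryCatch(forward_model(connectome(W, sc$regions), seeds),
                       error = function(e)
                         stop("forward model failed at epoch ", t, ": ",
                              conditionMessage(e)))
    delta <- fc_target[hom] - fc_sim[hom]
    err[t] <- mean(abs(delta))
    if (t > 1 && err[t] > err[t - 1]) grew <- grew + 1L else grew <- 0L
    if (grew >= 2L) { eta <- eta / 2; grew <- 0L }
    W[hom] <- pmax(0, W[hom] + eta * delta)
    W <- (W + t(W)) / 2  # exact symmetry (updates are pairwise symmetric)
    if (verbose) message("epoch ", t, " homotopic error ", signif(err[t], 4))
  }
  out <- connectome(W, sc$regions)
  attr(out, "error") <- err
  out
}

#' Wilson-Cowan forward model for homotopic enhancement
#'
#' Returns a `function(connectome, seeds)` suitable for
#' [enhance_homotopic()], running the package's own neural mass +
#' hemodynamics forward model and averaging the FC over seeds.
#'
#' @param config a [sim_config()].
#' @param hemo a [hemo_config()].
#' @param TR,band BOLD sampling and band-pass settings.
#' @return A forward-model closure.
#' @export
wc_forward_model <- function(config = desk_sim_config(),
                             hemo = hemo_config(), TR = 2,
                             band = c(0.01, 0.1)) {
  function(conn, seeds) {
    fcs <- lapply(seeds, function(s)
      compute_fc(simulate_bold(conn, config, hemo, seed = s, TR = TR,
                               band = band)$bold))
    group_mean_fc(fcs)
  }
}
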