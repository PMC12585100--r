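#' Equidistant parameter grid
#'
#' Inclusive of both endpoints with exactly `n` values (spacing
#' `(hi - lo) / (n - 1)`), so standard optima such as `dsigma = -0.0204...`
#' are representable grid values.
#'
#' @param n number of grid points.
#' @param range `c(lo, hi)`.
#' @return Numeric vector of length `n`.
#' @export
make_grid <- function(n, range) {
  stopifnot(n >= 1, length(range) == 2, range[1] <= range[2])
  if (n == 1) return(mean(range))
  seq(range[1], range[2], length.out = n)
}

# tie-break comparator shared by run_sweep and select_optimum:
# smallest seed-aggregate fit, then smallest |dG|, then smallest |dsigma|,
# then earliest linear (column-major) grid index
best_grid_point <- function(agg, dG_grid, ds_grid) {
  finite <- is.finite(agg)
  if (!any(finite)) stop("no feasible grid point: all fit values are infinite")
  mn <- min(agg[finite])
  cand <- which(agg <= mn & finite, arr.ind = TRUE)
  ord <- order(abs(dG_grid[cand[, 1]]), abs(ds_grid[cand[, 2]]),
               (cand[, 2] - 1) * nrow(agg) + cand[, 1])
  unname(cand[ord[1], , drop = TRUE])
}

#' Sweep neuromodulation offsets against an empirical FC
#'
#' Runs the forward model over a `(dG, dsigma)` grid. At each grid point and
#' seed, regional parameters come from [apply_modulation()] with the given
#' maps (homogeneous when `NULL`), the model is simulated, BOLD is computed
#' and band-passed, and the euccorrelation between the simulated and
#' empirical FC lower triangles is recorded. Grid points whose parameters
#' are infeasible (nonpositive slope or negative coupling) are recorded as
#' `Inf`, as are isolated simulation failures. Seed `s` reuses
#' `seed + s - 1` at every grid point (common random numbers across the
#' grid, and bitwise equality between a homogeneous sweep and a unit-map
#' sweep).
#'
#' An absolute `(G, sigma)` baseline sweep is the special case
#' `baseline = c(0, 0)` with homogeneous maps and grids spanning the
#' absolute ranges.
#'
#' @param empirical_fc target FC matrix.
#' @param connectome a [connectome()] or weight matrix.
#' @param maps `list(ach = , na = )` of normalized [modulation_map()]s, or
#'   `NULL` for homogeneous modulation.
#' @param baseline `c(G, sigma)` homogeneous baseline (typically the fitted
#'   wake optimum).
#' @param dG_grid,dsigma_grid grids from [make_grid()].
#' @param n_seeds simulation seeds per grid point.
#' @param config a [sim_config()]; its `G`/`sigma_E` fields are overridden
#'   per grid point.
#' @param hemo a [hemo_config()].
#' @param TR,band BOLD sampling interval and band-pass corners.
#' @param seed base RNG seed.
#' @param modality label: `"homogeneous"`, `"map"` or `"shuffle"`.
#' @param aggregate seed-aggregation rule for the optimum, `"mean"` (default)
#'   or `"median"`.
#' @return Object of class `fc_sweep`: `fit` (dG x dsigma x seed array),
#'   grids, `optimum`, `optimum_fcs` (per-seed simulated FCs at the optimum),
#'   baseline, modality, seeds.
#' @export
run_sweep <- function(empirical_fc, connectome, maps = NULL,
                      baseline = c(G = 0.14, sigma = 7.7),
                      dG_grid = make_grid(50, c(-0.5, 0.5)),
                      dsigma_grid = make_grid(50, c(-1, 1)),
                      n_seeds = 5, config = desk_sim_config(),
                      hemo = hemo_config(), TR = 2, band = c(0.01, 0.1),
                      seed = 1,
                      modality = c("homogeneous", "map", "shuffle"),
                      aggregate = c("mean", "median")) {
  modality <- match.arg(modality)
  aggregate <- match.arg(aggregate)
  empirical_fc <- check_fc(empirical_fc)
  emp_vec <- lower_triangle_vector(empirical_fc)
  C <- conn_weights(connectome)
  n <- nrow(C)
  ach <- if (is.null(maps)) NULL else maps$ach
  na_m <- if (is.null(maps)) NULL else maps$na
  nG <- length(dG_grid); nS <- length(dsigma_grid)
  fit <- array(Inf, dim = c(nG, nS, n_seeds))
  seeds <- seed + seq_len(n_seeds) - 1L
  failures <- character(0)

  run_one <- function(mod, s) {
    cfg <- config
    cfg$G <- mod$G_i
    cfg$sigma_E <- mod$sigma_E_i
    compute_fc(simulate_bold(connectome, cfg, hemo, seed = s, TR = TR,
                             band = band)$bold)
  }

  for (i in seq_len(nG)) {
    for (j in seq_len(nS)) {
      mod <- tryCatch(
        apply_modulation(baseline[1], baseline[2], dG_grid[i],
                         dsigma_grid[j], ach, na_m, n = n),
        error = function(e) NULL)
      if (is.null(mod)) next  # infeasible point stays Inf
      for (s in seq_len(n_seeds)) {
        val <- tryCatch(
          euccorrelation(lower_triangle_vector(run_one(mod, seeds[s])),
                         emp_vec),
          error = function(e) {
            failures <<- c(failures,
                           sprintf("(%g, %g) seed %d: %s", dG_grid[i],
                                   dsigma_grid[j], seeds[s],
                                   conditionMessage(e)))
            Inf
          })
        fit[i, j, s] <- val
      }
    }
  }
  obj <- structure(list(fit = fit, dG_grid = dG_grid,
                        dsigma_grid = dsigma_grid, baseline = baseline,
                        modality = modality, seeds = seeds,
                        aggregate = aggregate, failures = failures),
                   class = "fc_sweep")
  obj$optimum <- select_optimum(obj)
  # per-seed simulated FCs at the optimum, reproduced from the stored seeds
  opt_mod <- apply_modulation(baseline[1], baseline[2], obj$optimum$dG,
                              obj$optimum$dsigma, ach, na_m, n = n)
  obj$optimum_fcs <- lapply(seeds, function(s) run_one(opt_mod, s))
  if (length(failures) > 0)
    warning(length(failures), " grid-point simulations failed and were ",
            "recorded as Inf")
  obj
}

#' Select the optimal grid point of a sweep
#'
#' Argmin over the grid of the seed-aggregated (mean by default) fit. Exact
#' ties are broken toward the smallest `|dG|`, then smallest `|dsigma|`,
#' then the earlier grid index, deterministically.
#'
#' @param sweep an `fc_sweep`.
#' @param aggregate override the sweep's aggregation rule.
#' @return List with `dG`, `dsigma`, grid indices `i`, `j`, the aggregated
#'   `value`, and the per-seed fits at the optimum.
#' @export
select_optimum <- function(sweep, aggregate = NULL) {
  stopifnot(inherits(sweep, "fc_sweep"))
  aggregate <- if (is.null(aggregate)) sweep$aggregate else aggregate
  agg <- apply(sweep$fit, c(1, 2),
               if (aggregate == "median") stats::median else mean)
  idx <- best_grid_point(agg, sweep$dG_grid, sweep$dsigma_grid)
  i <- idx[1]; j <- idx[2]
  list(dG = sweep$dG_grid[i], dsigma = sweep$dsigma_grid[j], i = i, j = j,
       value = agg[i, j], seed_fits = sweep$fit[i, j, ])
}

#' @export
print.fc_sweep <- function(x, ...) {
  cat("FC sweep (", x$modality, " modulation): ", length(x$dG_grid), " x ",
      length(x$dsigma_grid), " grid, ", length(x$seeds), " seeds\n", sep = "")
  cat("  baseline G =", x$baseline[1], ", sigma =", x$baseline[2], "\n")
  cat("  optimum: dG =", signif(x$optimum$dG, 4),
      ", dsigma =", signif(x$optimum$dsigma, 4),
      " (", x$aggregate, " euccorrelation ", signif(x$optimum$value, 5),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.fc_sweep <- function(object, ...) {
  agg <- apply(object$fit, c(1, 2), mean)
  out <- list(modality = object$modality, optimum = object$optimum,
              landscape = agg, dG_grid = object$dG_grid,
              dsigma_grid = object$dsigma_grid,
              n_infeasible = sum(!is.finite(object$fit)))
  class(out) <- "summary.fc_sweep"
  out
}

#' @export
print.summary.fc_sweep <- function(x, ...) {
  cat("FC sweep summary (", x$modality, ")\n", sep = "")
  cat("  optimum: dG =", signif(x$optimum$dG, 4), ", dsigma =",
      signif(x$optimum$dsigma, 4), ", fit =", signif(x$optimum$value, 5), "\n")
  cat("  infeasible/failed entries:", x$n_infeasible, "\n")
  fin <- x$landscape[is.finite(x$landscape)]
  cat("  fit landscape range:", signif(min(fin), 4), "-",
      signif(max(fin), 4), "\n")
  invisible(x)
}

#' @export
coef.fc_sweep <- function(object, ...) {
  c(dG = object$optimum$dG, dsigma = object$optimum$dsigma)
}

#' @export
plot.fc_sweep <- function(x, ...) {
  agg <- apply(x$fit, c(1, 2), mean)
  agg[!is.finite(agg)] <- NA
  graphics::image(x$dG_grid, x$dsigma_grid, agg, xlab = "dG",
                  ylab = "dsigma",
                  main = paste("euccorrelation fit,", x$modality), ...)
  graphics::points(x$optimum$dG, x$optimum$dsigma, pch = 4, cex = 2)
  invisible(x)
}

#' Integration/segregation profile similarity
#'
#' For each simulated FC, the Pearson correlation between its nodal
#' integration (segregation) components and those of the empirical FC, both
#' from [hma_decompose()].
#'
#' @param simulated_fcs list of FC matrices (e.g. `sweep$optimum_fcs`).
#' @param empirical_fc target FC matrix.
#' @return Data frame with columns `r_integration`, `r_segregation`, one row
#'   per simulated FC.
#' @export
profile_similarity <- function(simulated_fcs, empirical_fc) {
  emp <- hma_decompose(check_fc(empirical_fc))
  if (sd(emp$H_in_nodal) == 0 || sd(emp$H_se_nodal) == 0)
    stop("degenerate empirical nodal profile (constant)")
  res <- t(vapply(simulated_fcs, function(fc) {
    h <- hma_decompose(check_fc(fc))
    if (sd(h$H_in_nodal) == 0 || sd(h$H_se_nodal) == 0)
      stop("degenerate simulated nodal profile (constant)")
    c(cor(h$H_in_nodal, emp$H_in_nodal), cor(h$H_se_nodal, emp$H_se_nodal))
  }, numeric(2)))
  data.frame(r_integration = res[, 1], r_segregation = res[, 2])
}

#' Effect sizes between modulation modalities
#'
#' Cohen's D between per-seed optimal-fit distributions for the modality
#' pairs map-homogeneous and map-shuffle (negative D means the map modality
#' fits better, i.e. lower euccorrelation), and, when `empirical_fc` is
#' given, between the integration/segregation profile correlations of
#' [profile_similarity()] (positive D means the map modality tracks the
#' empirical profile better).
#'
#' @param sweeps named list of `fc_sweep` objects; names among
#'   `"homogeneous"`, `"map"`, `"shuffle"`, with `"map"` present.
#' @param empirical_fc optional FC matrix for profile comparisons.
#' @return Data frame with columns `metric`, `comparison`, `d`, `bin`.
#' @export
compare_modalities <- function(sweeps, empirical_fc = NULL) {
  stopifnot("map" %in% names(sweeps))
  ns <- vapply(sweeps, function(s) length(s$seeds), integer(1))
  if (length(unique(ns)) != 1)
    stop("all sweeps must use the same number of seeds")
  if (ns[1] < 2) stop("need at least 2 seeds per modality")
  others <- intersect(c("homogeneous", "shuffle"), names(sweeps))
  rows <- list()
  add <- function(metric, cmp, x, y) {
    es <- cohens_d(x, y, paired = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric,
                                            comparison = cmp, d = es$d,
                                            bin = es$bin)
  }
  map_fit <- sweeps$map$optimum$seed_fits
  prof_map <- if (!is.null(empirical_fc))
    profile_similarity(sweeps$map$optimum_fcs, empirical_fc)
  for (o in others) {
    cmp <- paste0("map-", if (o == "homogeneous") "homo" else o)
    add("fit", cmp, map_fit, sweeps[[o]]$optimum$seed_fits)
    if (!is.null(empirical_fc)) {
      prof_o <- profile_similarity(sweeps[[o]]$optimum_fcs, empirical_fc)
      add("r_integration", cmp, prof_map$r_integration, prof_o$r_integration)
      add("r_segregation", cmp, prof_map$r_segregation, prof_o$r_segregation)
    }
  }
  do.call(rbind, rows)
}
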