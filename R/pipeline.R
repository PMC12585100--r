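#' Run manifest
#'
#' Provenance record for a workflow run: package version, timestamp, seeds,
#' configuration snapshot and input digests (md5 of any file paths given).
#'
#' @param config list of configuration objects (stored as-is).
#' @param seeds integer seeds used.
#' @param inputs named character vector of input file paths to digest, or
#'   `NULL`.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = integer(0), inputs = NULL) {
  digests <- if (is.null(inputs)) NULL else
    vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  structure(list(package = "sleepwc",
                 version = as.character(utils::packageVersion("sleepwc")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seeds = seeds, config = config, input_digests = digests),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Empirical FC analysis workflow
#'
#' Stage-wise analysis of a multi-subject dataset: per-subject FC matrices,
#' group-mean FC, nodal strengths, nucleus-to-cortex FC vectors (with the
#' PPN confound regressed out of the LC signal when both are present), and
#' HMA integration/segregation profiles; plus cross-stage statistics against
#' wake (area-paired t-tests with BH correction and Cohen's D on nodal
#' strength and nucleus FC) and correlations of the wake nucleus-FC vectors
#' with the wake nodal HMA components.
#'
#' @param datasets list of [stage_dataset()] objects (complete subjects are
#'   selected automatically).
#' @param nucleus_names names of nucleus signals to analyse when present.
#' @param confounds named character vector mapping a nucleus to its confound
#'   signal (default regresses PPN out of LC).
#' @param fisher_z average subject FCs on the Fisher-z scale.
#' @param alpha significance level for BH-adjusted tests.
#' @return List of class `empirical_result` with elements `subjects`,
#'   `stages` (per-stage lists), `cross_stage` (tests and effect sizes vs W),
#'   `nucleus_vs_hma`, `manifest`.
#' @export
empirical_workflow <- function(datasets, nucleus_names = c("BF", "LC"),
                               confounds = c(LC = "PPN"), fisher_z = FALSE,
                               alpha = 0.05) {
  subjects <- select_complete_subjects(datasets)
  if (length(subjects) == 0) stop("no subject has data in all four stages")
  ids <- vapply(datasets, function(d) d$subject_id, character(1))
  stg <- vapply(datasets, function(d) d$stage, character(1))

  get_ds <- function(sub, stage) {
    hit <- which(ids == sub & stg == stage)
    segs <- lapply(datasets[hit], function(d) d$series)
    series <- concatenate_stage_volumes(segs)
    nuc <- datasets[[hit[1]]]$nucleus_series
    list(series = series, nucleus = nuc)
  }

  stages_out <- list()
  for (stage in STAGES) {
    fcs <- list(); strengths <- list()
    nuc_fc <- lapply(nucleus_names, function(x) list())
    names(nuc_fc) <- nucleus_names
    for (sub in subjects) {
      d <- get_ds(sub, stage)
      fc <- compute_fc(d$series)
      fcs[[sub]] <- fc
      strengths[[sub]] <- nodal_strength(fc)
      for (nm in nucleus_names) {
        if (is.null(d$nucleus) || is.null(d$nucleus[[nm]])) next
        sig <- d$nucleus[[nm]]
        cf <- confounds[nm]
        if (!is.na(cf) && !is.null(d$nucleus[[cf]]))
          sig <- regress_confound(sig, d$nucleus[[cf]])
        nuc_fc[[nm]][[sub]] <- nucleus_fc(sig, d$series)
      }
    }
    gfc <- group_mean_fc(fcs, fisher_z = fisher_z)
    str_mat <- do.call(rbind, strengths)
    nuc_mean <- lapply(nuc_fc, function(lst)
      if (length(lst) > 0) colMeans(do.call(rbind, lst)) else NULL)
    stages_out[[stage]] <- list(
      subject_fcs = fcs, group_fc = gfc,
      nodal_strength = colMeans(str_mat),
      nucleus_fc = nuc_mean,
      hma = hma_decompose(gfc))
  }

  # cross-stage comparisons vs W, paired by brain area (mean across subjects)
  cross <- list()
  strength_groups <- lapply(stages_out, function(s) s$nodal_strength)
  cross$nodal_strength <- list(
    tests = paired_tests_bh(strength_groups, alpha = alpha),
    effect_sizes = lapply(setdiff(STAGES, "W"), function(stage)
      cohens_d(stages_out[[stage]]$nodal_strength,
               stages_out$W$nodal_strength, paired = TRUE)))
  names(cross$nodal_strength$effect_sizes) <- setdiff(STAGES, "W")
  for (nm in nucleus_names) {
    vecs <- lapply(stages_out, function(s) s$nucleus_fc[[nm]])
    if (any(vapply(vecs, is.null, logical(1)))) next
    cross[[paste0(nm, "_fc")]] <- list(
      tests = paired_tests_bh(vecs, alpha = alpha),
      effect_sizes = setNames(lapply(setdiff(STAGES, "W"), function(stage)
        cohens_d(vecs[[stage]], vecs$W, paired = TRUE)),
        setdiff(STAGES, "W")))
  }

  # wake nucleus-FC profiles vs wake nodal integration / segregation
  nucleus_vs_hma <- list()
  hW <- stages_out$W$hma
  for (nm in nucleus_names) {
    v <- stages_out$W$nucleus_fc[[nm]]
    if (is.null(v)) next
    nucleus_vs_hma[[nm]] <- list(
      integration = stats::cor.test(v, hW$H_in_nodal),
      segregation = stats::cor.test(v, hW$H_se_nodal))
  }

  structure(list(subjects = subjects, stages = stages_out,
                 cross_stage = cross, nucleus_vs_hma = nucleus_vs_hma,
                 manifest = run_manifest(config = list(fisher_z = fisher_z,
                                                       alpha = alpha))),
            class = "empirical_result")
}

#' @export
print.empirical_result <- function(x, ...) {
  cat("Empirical FC analysis:", length(x$subjects), "complete subjects\n")
  for (stage in STAGES) {
    s <- x$stages[[stage]]
    cat(sprintf("  %-2s: mean strength %6.3f, H_in %7.4f, H_se %7.4f\n",
                stage, mean(s$nodal_strength), s$hma$H_in, s$hma$H_se))
  }
  invisible(x)
}

#' Model fitting workflow
#'
#' The full fitting protocol against per-stage empirical FC matrices: an
#' absolute homogeneous `(G, sigma)` sweep on the wake FC fixes the
#' baseline; per stage and modality (homogeneous, map, shuffled map),
#' `(dG, dsigma)` offset sweeps from that baseline select optima; modality
#' effect sizes and integration/segregation profile similarities are
#' computed per stage.
#'
#' @param stage_fcs named list of empirical FC matrices for `W`, `N1`, `N2`,
#'   `N3` (at least `W`).
#' @param connectome a [connectome()].
#' @param maps `list(ach = , na = )` of normalized [modulation_map()]s.
#' @param G_grid,sigma_grid absolute grids for the wake baseline sweep.
#' @param dG_grid,dsigma_grid offset grids for the stage sweeps.
#' @param n_seeds seeds per grid point.
#' @param config,hemo,TR,band forward-model settings.
#' @param seed base RNG seed.
#' @param shuffle_seed seed of the map-shuffling surrogate.
#' @param modalities subset of `c("homogeneous", "map", "shuffle")` to run.
#' @return List of class `fitting_result`: `baseline` (wake `fc_sweep`),
#'   `stages` (per stage: sweeps by modality, `comparison` table), `manifest`.
#' @export
fitting_workflow <- function(stage_fcs, connectome, maps,
                             G_grid = make_grid(11, c(0, 0.3)),
                             sigma_grid = make_grid(11, c(1, 12)),
                             dG_grid = make_grid(11, c(-0.5, 0.5)),
                             dsigma_grid = make_grid(11, c(-1, 1)),
                             n_seeds = 5, config = desk_sim_config(),
                             hemo = hemo_config(), TR = 2,
                             band = c(0.01, 0.1), seed = 1,
                             shuffle_seed = 1,
                             modalities = c("homogeneous", "map", "shuffle")) {
  stopifnot("W" %in% names(stage_fcs))
  regions <- conn_regions(connectome)
  base_sweep <- run_sweep(stage_fcs$W, connectome, maps = NULL,
                          baseline = c(G = 0, sigma = 0),
                          dG_grid = G_grid, dsigma_grid = sigma_grid,
                          n_seeds = n_seeds, config = config, hemo = hemo,
                          TR = TR, band = band, seed = seed,
                          modality = "homogeneous")
  baseline <- c(G = base_sweep$optimum$dG, sigma = base_sweep$optimum$dsigma)

  shuffled <- list(
    ach = shuffle_map_hemisymmetric(maps$ach, regions, seed = shuffle_seed),
    na = shuffle_map_hemisymmetric(maps$na, regions, seed = shuffle_seed + 1))

  modality_maps <- list(homogeneous = NULL, map = maps, shuffle = shuffled)
  stages_out <- list()
  for (stage in intersect(STAGES, names(stage_fcs))) {
    sweeps <- list()
    for (m in modalities) {
      sweeps[[m]] <- run_sweep(stage_fcs[[stage]], connectome,
                               maps = modality_maps[[m]],
                               baseline = baseline, dG_grid = dG_grid,
                               dsigma_grid = dsigma_grid, n_seeds = n_seeds,
                               config = config, hemo = hemo, TR = TR,
                               band = band, seed = seed, modality = m)
    }
    comparison <- if ("map" %in% modalities && length(modalities) > 1)
      compare_modalities(sweeps, empirical_fc = stage_fcs[[stage]]) else NULL
    stages_out[[stage]] <- list(sweeps = sweeps, comparison = comparison)
  }
  structure(list(baseline_sweep = base_sweep, baseline = baseline,
                 shuffled_maps = shuffled, stages = stages_out,
                 manifest = run_manifest(
                   config = list(G_grid = G_grid, sigma_grid = sigma_grid,
                                 dG_grid = dG_grid,
                                 dsigma_grid = dsigma_grid,
                                 n_seeds = n_seeds, TR = TR, band = band),
                   seeds = c(seed, shuffle_seed))),
            class = "fitting_result")
}

#' @export
print.fitting_result <- function(x, ...) {
  cat("Model fitting workflow\n")
  cat("  wake baseline: G =", signif(x$baseline[1], 4), ", sigma =",
      signif(x$baseline[2], 4), "\n")
  for (stage in names(x$stages)) {
    cat("  ", stage, ":\n", sep = "")
    for (m in names(x$stages[[stage]]$sweeps)) {
      o <- x$stages[[stage]]$sweeps[[m]]$optimum
      cat(sprintf("    %-11s dG = %7.4f, dsigma = %7.4f, fit = %.4f\n",
                  m, o$dG, o$dsigma, o$value))
    }
  }
  invisible(x)
}
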