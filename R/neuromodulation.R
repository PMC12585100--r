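#' Construct a modulation map
#'
#' A per-region positive weight vector describing the regional receptivity of
#' a neuromodulator (e.g. vesicular ACh transporter density for ACh, locus
#' coeruleus structural projections for NA).
#'
#' @param values positive numeric vector of length N.
#' @param kind one of `"ACh"`, `"NA"`, `"surrogate"`.
#' @param normalized has the mean-1 normalization been applied?
#' @return Object of class `modulation_map`.
#' @export
modulation_map <- function(values, kind = c("ACh", "NA", "surrogate"),
                           normalized = FALSE) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("modulation map values must be positive and finite")
  if (normalized && abs(mean(values) - 1) > 1e-10)
    stop("map marked normalized but mean differs from 1")
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "modulation_map")
}

#' @export
print.modulation_map <- function(x, ...) {
  cat("Modulation map (", x$kind, "): ", length(x$values), " regions, mean ",
      round(mean(x$values), 4),
      if (x$normalized) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

map_values <- function(m) if (inherits(m, "modulation_map")) m$values else as.numeric(m)

#' Normalize a raw regional map to mean 1
#'
#' Optionally de-escalates thalamic entries first: values at thalamic regions
#' are clipped to the maximum over non-thalamic regions (used for projection
#' maps whose thalamic values dwarf the cortex and would otherwise dominate
#' the normalization), then the vector is divided by its mean.
#'
#' @param raw positive numeric vector.
#' @param regions region table (required when `deescalate_thalamus`).
#' @param deescalate_thalamus clip thalamic entries before normalizing.
#' @param kind map kind label, passed to [modulation_map()].
#' @return A normalized [modulation_map()].
#' @export
normalize_map <- function(raw, regions = NULL, deescalate_thalamus = FALSE,
                          kind = "ACh") {
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("raw map values must be positive and finite")
  if (deescalate_thalamus) {
    if (is.null(regions)) stop("regions required to locate thalamic entries")
    validate_region_table(regions)
    th <- which(regions$is_thalamus)
    if (length(th) > 0 && length(th) < length(raw)) {
      cap <- max(raw[-th])
      raw[th] <- pmin(raw[th], cap)
    }
  }
  modulation_map(raw / mean(raw), kind = kind, normalized = TRUE)
}

#' Build per-region coupling and slope fields
#'
#' Regional parameter values under neuromodulation:
#' `G_i = G + dG * ACh_i` and `sigma_E_i = sigma + dsigma * NA_i`.
#' With `NULL` maps the modulation is homogeneous (maps identically 1).
#' A nonpositive resulting slope or negative coupling is an error (the
#' sigmoid is undefined for `sigma <= 0`); sweeps catch this and record the
#' grid point as infeasible.
#'
#' @param G,sigma homogeneous baseline coupling and slope.
#' @param dG,dsigma modulation offsets (swept during fitting).
#' @param ach,na normalized [modulation_map()]s or `NULL`.
#' @param n number of regions (needed when both maps are `NULL`).
#' @return List with vectors `G_i`, `sigma_E_i`.
#' @export
apply_modulation <- function(G, sigma, dG = 0, dsigma = 0, ach = NULL,
                             na = NULL, n = NULL) {
  len <- if (!is.null(ach)) length(map_values(ach))
         else if (!is.null(na)) length(map_values(na))
         else n
  if (is.null(len)) stop("give n when both maps are NULL")
  av <- if (is.null(ach)) rep(1, len) else map_values(ach)
  nv <- if (is.null(na)) rep(1, len) else map_values(na)
  if (length(av) != len || length(nv) != len) stop("map lengths differ")
  G_i <- G + dG * av
  sigma_E_i <- sigma + dsigma * nv
  if (any(sigma_E_i <= 0))
    stop("parameter-range error: nonpositive excitatory slope at region ",
         which(sigma_E_i <= 0)[1])
  if (any(G_i < 0))
    stop("parameter-range error: negative coupling at region ",
         which(G_i < 0)[1])
  list(G_i = G_i, sigma_E_i = sigma_E_i)
}

#' Hemisphere-symmetric map shuffling surrogate
#'
#' Draws one random permutation of the homotopic-pair values and applies it
#' identically to both hemispheres, so homotopic correspondence (and hence
#' the map's correlation with a homotopically symmetric connectome) is
#' structurally preserved. The multiset of values and each hemisphere's mean
#' are conserved exactly. With `joint = FALSE` each hemisphere is permuted
#' independently instead.
#'
#' @param map a [modulation_map()] or numeric vector.
#' @param regions region table with complete homotopic pairing.
#' @param seed integer RNG seed.
#' @param joint permute pairs jointly across hemispheres (default).
#' @return A [modulation_map()] of kind `"surrogate"`.
#' @export
shuffle_map_hemisymmetric <- function(map, regions, seed = 1, joint = TRUE) {
  validate_region_table(regions)
  v <- map_values(map)
  n <- length(v)
  if (nrow(regions) != n) stop("map length does not match region table")
  left <- which(regions$hemisphere == "left")
  right <- as.integer(regions$homotopic_partner[left])
  set.seed(seed)
  out <- v
  if (joint) {
    perm <- sample(length(left))
    out[left] <- v[left[perm]]
    out[right] <- v[right[perm]]
  } else {
    out[left] <- v[left[sample(length(left))]]
    out[right] <- v[right[sample(length(right))]]
  }
  m <- modulation_map(out, kind = "surrogate",
                      normalized = abs(mean(out) - 1) <= 1e-10)
  m$seed <- seed
  m
}

#' Read/write modulation maps as two-column TSV
#'
#' Files have columns `region_id`, `value`.
#'
#' @param path file path.
#' @param kind map kind for the reader.
#' @return For the reader, a [modulation_map()].
#' @export
read_map <- function(path, kind = "ACh") {
  tab <- read.table(path, header = TRUE, sep = "\t")
  v <- tab$value[order(tab$region_id)]
  modulation_map(v, kind = kind, normalized = abs(mean(v) - 1) <= 1e-10)
}

#' @rdname read_map
#' @param map a [modulation_map()].
#' @export
write_map <- function(map, path) {
  v <- map_values(map)
  write.table(data.frame(region_id = seq_along(v), value = v), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  # surrogates carry their shuffle seed in a sidecar for provenance
  if (inherits(map, "modulation_map") && map$kind == "surrogate" &&
      !is.null(map$seed))
    jsonlite::write_json(list(kind = "surrogate", seed = map$seed),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
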