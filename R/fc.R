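#' Functional connectivity matrix
#'
#' Pairwise Pearson correlations between regional time series.
#'
#' @param series region-by-time numeric matrix (or a [bold_series()]).
#' @return N x N correlation matrix with unit diagonal.
#' @export
compute_fc <- function(series) {
  if (inherits(series, "bold_series")) series <- series$values
  series <- as.matrix(series)
  if (ncol(series) < 3) stop("need at least 3 time points for FC")
  sds <- apply(series, 1, sd)
  if (any(sds == 0))
    stop("degenerate signal: region ", which(sds == 0)[1],
         " is constant; its correlations are undefined")
  fc <- cor(t(series))
  diag(fc) <- 1
  dimnames(fc) <- NULL
  fc
}

check_fc <- function(fc) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc) || max(abs(fc - t(fc))) > 1e-8)
    stop("FC matrix must be square and symmetric")
  fc
}

#' Strict lower triangle as a vector
#'
#' Row-major order over entries with `i > j`: (2,1), (3,1), (3,2), (4,1), ...
#'
#' @param fc square matrix.
#' @return Numeric vector of length `N (N - 1) / 2`.
#' @export
lower_triangle_vector <- function(fc) {
  fc <- as.matrix(fc)
  t(fc)[upper.tri(fc)]
}

#' Euccorrelation fit semi-metric
#'
#' Euclidean distance between two vectors divided by the absolute Pearson
#' correlation between them: sensitive both to the overall connectivity
#' pattern (through the correlation) and to its strength (through the
#' distance). Lower is a better fit. A correlation of zero (within 1e-12)
#' yields `Inf`, so an argmin over a sweep never selects such a point.
#'
#' @param v1,v2 numeric vectors of equal length (at least 3), typically FC
#'   lower triangles from [lower_triangle_vector()].
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
euccorrelation <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("vectors have different lengths: ", length(v1), " vs ", length(v2))
  if (length(v1) < 3) stop("need at least 3 values")
  s1 <- sd(v1); s2 <- sd(v2)
  if (s1 == 0 && s2 == 0) stop("undefined correlation: both vectors constant")
  d <- sqrt(sum((v1 - v2)^2))
  if (s1 == 0 || s2 == 0) return(Inf)
  rho <- cor(v1, v2)
  if (abs(rho) < 1e-12) return(Inf)
  d / abs(rho)
}

#' Nodal functional strength
#'
#' Sum of incoming FC values per node (off-diagonal row sums).
#'
#' @param fc FC matrix.
#' @return Length-N numeric vector.
#' @export
nodal_strength <- function(fc) {
  fc <- check_fc(fc)
  rowSums(fc) - diag(fc)
}

#' Regress a confound out of a signal
#'
#' Ordinary least squares of `target` on `confound` plus intercept; returns
#' the residual, which is uncorrelated with the confound. Used to remove the
#' PPN time course from the LC signal before nucleus FC.
#'
#' @param target,confound numeric vectors of equal length.
#' @return Residual vector of the same length.
#' @export
regress_confound <- function(target, confound) {
  if (length(target) != length(confound)) stop("lengths differ")
  if (sd(confound) == 0) stop("degenerate confound: constant signal")
  as.numeric(residuals(lm(target ~ confound)))
}

#' Nucleus-to-cortex FC vector
#'
#' Pearson correlation of one nucleus signal (e.g. BF or LC) with every
#' regional series.
#'
#' @param nucleus numeric vector (1 x time).
#' @param regions_series region-by-time matrix with matching time length.
#' @return Length-N vector of correlations.
#' @export
nucleus_fc <- function(nucleus, regions_series) {
  regions_series <- as.matrix(regions_series)
  if (length(nucleus) != ncol(regions_series))
    stop("time lengths differ: nucleus ", length(nucleus), ", series ",
         ncol(regions_series))
  if (sd(nucleus) == 0) stop("degenerate nucleus signal: constant")
  sds <- apply(regions_series, 1, sd)
  if (any(sds == 0))
    stop("degenerate signal: region ", which(sds == 0)[1], " is constant")
  as.numeric(cor(nucleus, t(regions_series)))
}

#' Group-mean FC
#'
#' Element-wise mean of per-subject FC matrices. Optionally averages on the
#' Fisher-z scale and back-transforms.
#'
#' @param fc_list list of FC matrices of equal dimension.
#' @param fisher_z average on the z scale.
#' @return FC matrix.
#' @export
group_mean_fc <- function(fc_list, fisher_z = FALSE) {
  stopifnot(length(fc_list) >= 1)
  if (fisher_z) {
    zs <- lapply(fc_list, function(m) atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)))
    m <- tanh(Reduce(`+`, zs) / length(zs))
  } else {
    m <- Reduce(`+`, fc_list) / length(fc_list)
  }
  diag(m) <- 1
  m
}
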