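#' Construct a structural connectome
#'
#' A nonnegative, symmetric, zero-diagonal weight matrix with region metadata.
#'
#' @param weights numeric N x N matrix of connection weights (arbitrary units).
#' @param regions region table as from [make_region_table()]; defaults to a
#'   generic table with the standard left/right homotopic layout.
#' @return An object of class `connectome` with elements `weights`, `regions`.
#' @export
connectome <- function(weights, regions = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("connectome weights must be square")
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("connectome weights must be symmetric (tolerance 1e-10)")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero")
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  if (is.null(regions)) regions <- make_region_table(n)
  validate_region_table(regions)
  if (nrow(regions) != n) stop("region table does not match matrix dimension")
  structure(list(weights = weights, regions = regions), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Connectome:", n, "regions,", nz, "connections (density",
      round(nz / (n * (n - 1) / 2), 3), ")\n")
  invisible(x)
}

# accept either a connectome or a bare weight matrix
conn_weights <- function(x) {
  if (inherits(x, "connectome")) x$weights else as.matrix(x)
}

conn_regions <- function(x, n = NULL) {
  if (inherits(x, "connectome")) x$regions else make_region_table(n)
}
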