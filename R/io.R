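#' @useDynLib sleepwc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor sd coef lm pt qt p.adjust t.test rnorm runif setNames
#' @importFrom stats residuals var median cor.test
#' @importFrom utils read.table write.table head
NULL

# Sleep stages form a closed set; everything downstream is defined over these.
STAGES <- c("W", "N1", "N2", "N3")

#' Validate a sleep-stage label
#'
#' @param stage character scalar, one of `"W"`, `"N1"`, `"N2"`, `"N3"`.
#' @return The validated stage label.
#' @export
validate_stage <- function(stage) {
  if (!is.character(stage) || length(stage) != 1L || !(stage %in% STAGES))
    stop("unknown sleep stage '", paste(stage, collapse = ","),
         "'; must be one of ", paste(STAGES, collapse = ", "))
  stage
}

#' Build a region table with homotopic pairing
#'
#' Regions `1..n/2` form the left hemisphere, `n/2+1..n` the right; region
#' `i` is homotopically paired with `i + n/2`. Region ids are 1-based.
#'
#' @param n even number of regions.
#' @param labels optional character vector of region names.
#' @param thalamus integer vector of region ids flagged as thalamic.
#' @return A data.frame with columns `region_id`, `label`, `hemisphere`,
#'   `homotopic_partner`, `is_thalamus`.
#' @export
make_region_table <- function(n, labels = NULL, thalamus = integer(0)) {
  if (n < 2 || n %% 2 != 0) stop("n must be an even integer >= 2")
  half <- n / 2L
  if (is.null(labels))
    labels <- sprintf("R%03d_%s", rep(seq_len(half), 2),
                      rep(c("L", "R"), each = half))
  data.frame(
    region_id = seq_len(n),
    label = labels,
    hemisphere = rep(c("left", "right"), each = half),
    homotopic_partner = c(seq_len(half) + half, seq_len(half)),
    is_thalamus = seq_len(n) %in% thalamus,
    stringsAsFactors = FALSE
  )
}

#' Validate a region table
#'
#' Checks the homotopic pairing is an involution across hemispheres and that
#' region ids are `1..n`.
#'
#' @param regions a region table as from [make_region_table()].
#' @return The validated table, invisibly.
#' @export
validate_region_table <- function(regions) {
  need <- c("region_id", "label", "hemisphere", "homotopic_partner", "is_thalamus")
  if (!all(need %in% names(regions)))
    stop("region table lacks columns: ",
         paste(setdiff(need, names(regions)), collapse = ", "))
  n <- nrow(regions)
  if (!identical(as.integer(regions$region_id), seq_len(n)))
    stop("region_id must be 1..", n)
  if (!all(regions$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  p <- as.integer(regions$homotopic_partner)
  if (any(p < 1 | p > n)) stop("homotopic_partner out of range")
  if (!identical(p[p], seq_len(n)))
    stop("homotopic pairing is not an involution")
  if (any(regions$hemisphere[p] == regions$hemisphere))
    stop("homotopic partners must lie in opposite hemispheres")
  invisible(regions)
}

#' Read a square numeric matrix from tab-separated text
#'
#' @param path file path.
#' @param expected_n if given, the required dimension.
#' @return An `n x n` numeric matrix.
#' @export
read_matrix <- function(path, expected_n = NULL) {
  raw <- read.table(path, header = FALSE, sep = "", colClasses = "numeric")
  m <- as.matrix(raw)
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("matrix file '", path, "' is not numeric")
  if (nrow(m) != ncol(m))
    stop("matrix file '", path, "' is not square: ", nrow(m), " rows x ",
         ncol(m), " columns")
  if (!is.null(expected_n) && nrow(m) != expected_n)
    stop("matrix file '", path, "' has dimension ", nrow(m),
         ", expected ", expected_n)
  m
}

#' Write a numeric matrix as tab-separated text
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read/write a region table
#'
#' @param path file path (tab-separated, with header).
#' @return For `read_region_table`, the validated region table.
#' @export
read_region_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab$is_thalamus <- as.logical(tab$is_thalamus)
  validate_region_table(tab)
  tab
}

#' @rdname read_region_table
#' @param regions region table to write.
#' @export
write_region_table <- function(regions, path) {
  validate_region_table(regions)
  write.table(regions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a stage dataset
#'
#' One subject's region-by-time BOLD matrix in one sleep stage, with optional
#' auxiliary nucleus signals (e.g. BF, LC, PPN time courses).
#'
#' @param subject_id character scalar.
#' @param stage one of `"W"`, `"N1"`, `"N2"`, `"N3"`.
#' @param series numeric region-by-time matrix.
#' @param TR sampling interval in seconds.
#' @param nucleus_series optional named list of numeric vectors, each of the
#'   same length as `ncol(series)`.
#' @return An object of class `stage_dataset`.
#' @export
stage_dataset <- function(subject_id, stage, series, TR = 2,
                          nucleus_series = NULL) {
  validate_stage(stage)
  series <- as.matrix(series)
  if (anyNA(series)) stop("stage dataset has missing samples")
  if (ncol(series) < 2) stop("stage dataset needs at least 2 time points")
  if (!is.numeric(TR) || TR <= 0) stop("TR must be positive")
  if (!is.null(nucleus_series)) {
    stopifnot(is.list(nucleus_series), !is.null(names(nucleus_series)))
    for (nm in names(nucleus_series))
      if (length(nucleus_series[[nm]]) != ncol(series))
        stop("nucleus series '", nm, "' length does not match series")
  }
  structure(list(subject_id = as.character(subject_id), stage = stage,
                 series = series, TR = TR, nucleus_series = nucleus_series),
            class = "stage_dataset")
}

#' @export
print.stage_dataset <- function(x, ...) {
  cat("Stage dataset: subject", x$subject_id, "stage", x$stage, "-",
      nrow(x$series), "regions x", ncol(x$series), "volumes (TR =", x$TR, "s)\n")
  if (!is.null(x$nucleus_series))
    cat("  nucleus signals:", paste(names(x$nucleus_series), collapse = ", "), "\n")
  invisible(x)
}

#' Subjects with data in every sleep stage
#'
#' Returns the subject ids having at least one dataset in each of W, N1, N2
#' and N3, in stable input order.
#'
#' @param datasets list of [stage_dataset()] objects.
#' @return Character vector of subject ids (possibly empty).
#' @export
select_complete_subjects <- function(datasets) {
  if (length(datasets) == 0) return(character(0))
  ids <- vapply(datasets, function(d) d$subject_id, character(1))
  stg <- vapply(datasets, function(d) d$stage, character(1))
  keep <- vapply(unique(ids), function(s) all(STAGES %in% stg[ids == s]),
                 logical(1))
  unique(ids)[keep]
}

#' Concatenate same-stage volume segments
#'
#' @param segments list of region-by-time matrices sharing the region count.
#' @return The column-wise concatenation, in input order.
#' @export
concatenate_stage_volumes <- function(segments) {
  if (length(segments) == 0) stop("no segments to concatenate")
  nr <- vapply(segments, nrow, integer(1))
  if (length(unique(nr)) != 1)
    stop("segments have mismatched region counts: ",
         paste(unique(nr), collapse = ", "))
  do.call(cbind, segments)
}

#' Read/write a stage dataset timeseries file
#'
#' Series files are tab-separated region-by-time matrices named
#' `<subject>_<stage>.tsv`.
#'
#' @param dataset a [stage_dataset()].
#' @param dir directory for the file.
#' @return For the writer, the file path invisibly.
#' @export
write_stage_series <- function(dataset, dir) {
  path <- file.path(dir, paste0(dataset$subject_id, "_", dataset$stage, ".tsv"))
  write.table(format(dataset$series, digits = 17, trim = TRUE,
                     scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_stage_series
#' @param path path to a `<subject>_<stage>.tsv` file.
#' @param TR sampling interval in seconds.
#' @export
read_stage_series <- function(path, TR = 2) {
  base <- sub("\\.tsv$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  stage <- parts[length(parts)]
  subject <- paste(parts[-length(parts)], collapse = "_")
  m <- as.matrix(read.table(path, header = FALSE, sep = ""))
  dimnames(m) <- NULL
  stage_dataset(subject, stage, m, TR = TR)
}
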