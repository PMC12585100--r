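#' Cohen's d with interpretation bins
#'
#' Unpaired: difference of means over the pooled standard deviation
#' (n - 1 weights). Paired: mean of differences over the standard deviation
#' of differences. The absolute value is binned as very small (< 0.2),
#' small, medium, large, very large or huge at thresholds 0.2 / 0.5 / 0.8 /
#' 1.2 / 2; boundary values go to the higher bin.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired treat as matched pairs.
#' @return Object of class `effect_size`: `d`, `n1`, `n2`, `paired`, `bin`.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample")
  if (paired) {
    if (n1 != n2) stop("paired samples must have equal length")
    dif <- x - y
    s <- sd(dif)
    if (s == 0) {
      if (mean(dif) == 0) d <- 0
      else stop("degenerate: zero SD of differences with nonzero mean")
    } else d <- mean(dif) / s
  } else {
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
    if (sp == 0) {
      if (mean(x) == mean(y)) d <- 0
      else stop("degenerate: zero pooled SD with unequal means")
    } else d <- (mean(x) - mean(y)) / sp
  }
  structure(list(d = d, n1 = n1, n2 = n2, paired = paired,
                 bin = effect_size_bin(d)), class = "effect_size")
}

#' @rdname cohens_d
#' @param d numeric effect size value.
#' @export
effect_size_bin <- function(d) {
  a <- abs(d)
  cuts <- c(0.2, 0.5, 0.8, 1.2, 2)
  bins <- c("very small", "small", "medium", "large", "very large", "huge")
  bins[findInterval(a, cuts) + 1]  # boundaries land in the higher bin
}

#' @export
print.effect_size <- function(x, ...) {
  cat("Cohen's d = ", signif(x$d, 4), " (", x$bin, "; ",
      if (x$paired) "paired" else "unpaired", ", n = ", x$n1,
      if (!x$paired) paste0(" vs ", x$n2), ")\n", sep = "")
  invisible(x)
}

#' Paired t-tests with Benjamini-Hochberg correction
#'
#' Two-sided paired t-tests for a set of condition comparisons, with
#' step-up BH adjustment across the family.
#'
#' @param groups named list of numeric vectors, matched within comparisons
#'   (e.g. per-area values for each sleep stage).
#' @param comparisons list of character pairs `c(a, b)` naming entries of
#'   `groups`; defaults to every condition against the first.
#' @param alpha significance level applied to adjusted p-values.
#' @return Data frame with columns `comparison`, `t`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
paired_tests_bh <- function(groups, comparisons = NULL, alpha = 0.05) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(comparisons)) {
    ref <- names(groups)[1]
    comparisons <- lapply(names(groups)[-1], function(g) c(g, ref))
  }
  if (length(comparisons) < 1) stop("no comparisons requested")
  res <- lapply(comparisons, function(cp) {
    x <- groups[[cp[1]]]; y <- groups[[cp[2]]]
    if (length(x) != length(y)) stop("comparison ", paste(cp, collapse = "-"),
                                     ": unmatched lengths")
    if (length(x) < 2) stop("comparison ", paste(cp, collapse = "-"),
                            ": fewer than 2 pairs")
    d <- x - y
    if (sd(d) == 0) {
      # identical differences: t.test is undefined; identical samples are
      # a null result, a constant nonzero shift a certain one
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(x, y, paired = TRUE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(comparison = paste(cp, collapse = "-"),
               t = tstat, p_raw = p)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation between two repeatedly measured
#' variables, via the analysis-of-covariance formulation (shared slope,
#' subject-specific intercepts). Subjects contribute their within-subject
#' deviations only, so adding a per-subject constant changes nothing.
#' Degrees of freedom are `N_obs - N_subjects - 1`.
#'
#' @param subject_ids subject identifier per observation.
#' @param x,y numeric repeated measures.
#' @return List with `r`, `dof`, `p`.
#' @export
rmcorr <- function(subject_ids, x, y) {
  stopifnot(length(subject_ids) == length(x), length(x) == length(y))
  subject_ids <- as.character(subject_ids)
  keep <- rep(TRUE, length(x))
  for (s in unique(subject_ids)) {
    sel <- subject_ids == s
    if (sum(sel) < 2 || sd(x[sel]) == 0) {
      if (sd(x[sel]) == 0 && sum(sel) >= 2)
        warning("subject ", s, " has constant x; dropped")
      keep[sel] <- FALSE
    }
  }
  x <- x[keep]; y <- y[keep]; subject_ids <- subject_ids[keep]
  subs <- unique(subject_ids)
  if (length(subs) < 2) stop("need at least 2 usable subjects")
  f <- factor(subject_ids)
  fit <- lm(y ~ f + x)
  fit0 <- lm(y ~ f)
  ss_err <- sum(residuals(fit)^2)
  ss_x <- sum(residuals(fit0)^2) - ss_err
  slope <- coef(fit)[["x"]]
  r <- sign(slope) * sqrt(max(ss_x, 0) / (ss_x + ss_err))
  dof <- length(x) - length(subs) - 1L
  tval <- r * sqrt(dof / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), dof)
  list(r = unname(r), dof = dof, p = unname(p))
}
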