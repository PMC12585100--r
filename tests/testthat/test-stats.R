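test_that("Cohen's d matches its definition and bins", {
  x <- c(1, 2, 3, 4)
  e <- cohens_d(x, x, paired = TRUE)
  expect_equal(e$d, 0)
  expect_equal(e$bin, "very small")
  set.seed(1)
  a <- rnorm(1e4, 0, 1); b <- rnorm(1e4, 1, 1)
  expect_equal(cohens_d(a, b)$d, -1, tolerance = 0.1)
  expect_equal(cohens_d(a, b)$bin, "large")
  # antisymmetry
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  # bin boundaries assign to the higher bin
  expect_equal(effect_size_bin(1.5), "very large")
  expect_equal(effect_size_bin(c(0.2, 0.5, 0.8, 1.2, 2)),
               c("small", "medium", "large", "very large", "huge"))
  expect_equal(effect_size_bin(-2.5), "huge")
  expect_error(cohens_d(1, 2), "at least 2")
})

test_that("BH step-up adjustment follows the hand computation", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  out <- paired_tests_bh(g, list(c("a", "b")))
  expect_equal(out$t, 0)
  expect_equal(out$p_raw, 1)
  expect_false(out$significant)
  # the classic staircase: all adjusted to the largest ratio
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # single comparison: adjustment is the identity
  set.seed(2)
  g2 <- list(a = rnorm(10), b = rnorm(10) + 1)
  out2 <- paired_tests_bh(g2, list(c("a", "b")))
  expect_equal(out2$p_adjusted, out2$p_raw)
  # adjusted p monotone in raw-p rank across a family
  g3 <- list(w = rnorm(20), x = rnorm(20) + 0.2, y = rnorm(20) + 0.7,
             z = rnorm(20) + 1.5)
  out3 <- paired_tests_bh(g3, list(c("x", "w"), c("y", "w"), c("z", "w")))
  ord <- order(out3$p_raw)
  expect_true(all(diff(out3$p_adjusted[ord]) >= -1e-15))
})

test_that("default comparisons test every condition against the first", {
  set.seed(3)
  g <- list(W = rnorm(12), N1 = rnorm(12), N2 = rnorm(12), N3 = rnorm(12))
  out <- paired_tests_bh(g)
  expect_equal(out$comparison, c("N1-W", "N2-W", "N3-W"))
})

test_that("repeated-measures correlation isolates within-subject slopes", {
  # perfect within-subject slope despite a large between-subject offset
  r <- rmcorr(c("A", "A", "B", "B"), c(1, 2, 11, 12), c(1, 2, 5, 6))
  expect_equal(r$r, 1)
  expect_equal(r$dof, 1L)
  # sign symmetry
  x <- rep(1:5, 3); s <- rep(c("A", "B", "C"), each = 5)
  r2 <- rmcorr(s, x, -x + rep(c(0, 10, 20), each = 5))
  expect_equal(r2$r, -1)
  # invariance to per-subject constants
  set.seed(4)
  y <- x * 0.5 + rnorm(15, 0, 0.3)
  r3 <- rmcorr(s, x, y)
  r4 <- rmcorr(s, x + rep(c(0, 100, -50), each = 5),
               y + rep(c(7, -3, 2), each = 5))
  expect_equal(r3$r, r4$r, tolerance = 1e-10)
  expect_equal(r3$dof, 15L - 3L - 1L)
})

test_that("null repeated measures give near-zero correlation", {
  set.seed(5)
  s <- rep(sprintf("s%02d", 1:15), each = 50)
  r <- rmcorr(s, rnorm(750), rnorm(750))
  expect_lt(abs(r$r), 0.1)
  expect_gt(r$p, 0.001)
})

test_that("subjects with constant x are dropped with a warning", {
  expect_warning(
    r <- rmcorr(c("A", "A", "A", "B", "B", "C", "C"),
                c(1, 1, 1, 1, 2, 3, 5), c(1, 2, 3, 1, 2, 3, 5)),
    "constant x")
  expect_equal(r$r, 1)
  # everything dropped: hard error
  expect_error(suppressWarnings(
    rmcorr(c("A", "A", "B", "B"), c(1, 1, 2, 2), c(1, 2, 3, 4))),
    "2 usable subjects")
})
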