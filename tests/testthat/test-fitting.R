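make_test_sweep <- function(fit, dG_grid, ds_grid) {
  structure(list(fit = fit, dG_grid = dG_grid, dsigma_grid = ds_grid,
                 baseline = c(0, 0), modality = "homogeneous",
                 seeds = seq_len(dim(fit)[3]), aggregate = "mean",
                 failures = character(0)),
            class = "fc_sweep")
}

test_that("grids are inclusive and equidistant", {
  g <- make_grid(50, c(-1, 1))
  expect_length(g, 50)
  expect_equal(g[1], -1)
  expect_equal(g[50], 1)
  expect_equal(unique(round(diff(g), 12)), 2 / 49)
  # conventionally reported optima sit within half a grid step
  expect_lt(min(abs(make_grid(50, c(-1, 1)) - (-0.0204))), 1e-3)
  expect_lt(min(abs(make_grid(50, c(-0.5, 0.5)) - 0.18)), 0.0103)
})

test_that("optimum selection takes the seed-mean argmin", {
  fit <- array(5, dim = c(3, 3, 2))
  fit[2, 3, ] <- c(1, 2)
  sw <- make_test_sweep(fit, c(-0.1, 0, 0.1), c(-0.2, 0, 0.2))
  o <- select_optimum(sw)
  expect_equal(c(o$i, o$j), c(2, 3))
  expect_equal(o$value, 1.5)
  expect_equal(o$seed_fits, c(1, 2))
  # a single finite point wins regardless of position
  fit2 <- array(Inf, dim = c(3, 3, 2))
  fit2[3, 1, ] <- 7
  o2 <- select_optimum(make_test_sweep(fit2, c(-0.1, 0, 0.1),
                                       c(-0.2, 0, 0.2)))
  expect_equal(c(o2$i, o2$j), c(3, 1))
  expect_error(select_optimum(make_test_sweep(array(Inf, c(2, 2, 2)),
                                              c(0, 1), c(0, 1))),
               "no feasible")
})

test_that("exact ties break toward small |dG|, then |dsigma|, then index", {
  dG <- c(-0.1, 0, 0.1); ds <- c(-0.2, 0, 0.2)
  fit <- array(5, dim = c(3, 3, 1))
  fit[1, 2, ] <- 1; fit[3, 2, ] <- 1       # tie at dG = -0.1 vs +0.1
  o <- select_optimum(make_test_sweep(fit, c(-0.1, 0, 0.1), ds))
  expect_equal(o$i, 1L)  # equal |dG|: earlier grid index wins
  fit2 <- array(5, dim = c(3, 3, 1))
  fit2[2, 1, ] <- 1; fit2[3, 1, ] <- 1     # |0| beats |0.1|
  o2 <- select_optimum(make_test_sweep(fit2, dG, ds))
  expect_equal(o2$i, 2L)
  fit3 <- array(5, dim = c(3, 3, 1))
  fit3[2, 1, ] <- 1; fit3[2, 3, ] <- 1     # same dG: smaller |dsigma|... tie
  fit3[2, 2, ] <- 1                         # dsigma = 0 also tied: wins
  o3 <- select_optimum(make_test_sweep(fit3, dG, ds))
  expect_equal(c(o3$i, o3$j), c(2L, 2L))
})

test_that("sweeps have the contracted shape and record infeasible points", {
  conn <- tiny_connectome()
  cfg <- tiny_config()
  emp <- random_corr(8, seed = 1)
  # dsigma = -9 makes the slope nonpositive: recorded as Inf, not an error
  sw <- run_sweep(emp, conn, baseline = c(G = 0.14, sigma = 7.7),
                  dG_grid = c(-0.05, 0, 0.05), dsigma_grid = c(-9, 0, 1),
                  n_seeds = 2, config = cfg, seed = 3)
  expect_equal(dim(sw$fit), c(3, 3, 2))
  expect_true(all(sw$fit[, 1, ] == Inf))
  expect_true(all(is.finite(sw$fit[, 2:3, ])))
  expect_true(all(sw$fit >= 0))
  expect_equal(coef(sw), c(dG = sw$optimum$dG, dsigma = sw$optimum$dsigma))
  expect_length(sw$optimum_fcs, 2)
})

test_that("unit maps reproduce the homogeneous sweep bitwise", {
  conn <- tiny_connectome()
  cfg <- tiny_config()
  emp <- random_corr(8, seed = 2)
  unit <- list(ach = modulation_map(rep(1, 8), "ACh", normalized = TRUE),
               na = modulation_map(rep(1, 8), "NA", normalized = TRUE))
  grid_g <- c(-0.05, 0.05); grid_s <- c(-0.5, 0.5)
  sw_h <- run_sweep(emp, conn, maps = NULL, baseline = c(0.14, 7.7),
                    dG_grid = grid_g, dsigma_grid = grid_s, n_seeds = 2,
                    config = cfg, seed = 5, modality = "homogeneous")
  sw_m <- run_sweep(emp, conn, maps = unit, baseline = c(0.14, 7.7),
                    dG_grid = grid_g, dsigma_grid = grid_s, n_seeds = 2,
                    config = cfg, seed = 5, modality = "map")
  expect_identical(sw_h$fit, sw_m$fit)
})

test_that("profile similarity is 1 for identical FC and negative for
           rank-reversed profiles", {
  emp <- random_corr(10, seed = 4)
  ps <- profile_similarity(list(emp, emp), emp)
  expect_equal(nrow(ps), 2)
  expect_equal(ps$r_integration, c(1, 1))
  expect_equal(ps$r_segregation, c(1, 1))
  # two-block matrices with swapped block strengths anticorrelate in their
  # integration profiles
  blk <- function(a, b) {
    m <- matrix(0.05, 10, 10)
    m[1:5, 1:5] <- a; m[6:10, 6:10] <- b
    diag(m) <- 1
    m
  }
  ps2 <- profile_similarity(list(blk(0.2, 0.9)), blk(0.9, 0.2))
  expect_lt(ps2$r_integration, 0)
})

test_that("modality comparison produces signed binned effect sizes", {
  mk <- function(fits) {
    sw <- make_test_sweep(array(rep(fits, each = 1), c(1, 1, length(fits))),
                          0, 0)
    sw$optimum <- select_optimum(sw)
    sw$optimum_fcs <- replicate(length(fits), random_corr(6, 1),
                                simplify = FALSE)
    sw
  }
  base <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  sweeps <- list(map = mk(base), homogeneous = mk(base),
                 shuffle = mk(base + 1 * sd(base)))
  cmp <- compare_modalities(sweeps)
  d_homo <- cmp$d[cmp$comparison == "map-homo" & cmp$metric == "fit"]
  d_shuf <- cmp$d[cmp$comparison == "map-shuffle" & cmp$metric == "fit"]
  expect_equal(d_homo, 0)
  expect_equal(d_shuf, -1, tolerance = 1e-10)  # uniformly 1 pooled SD lower
  expect_equal(cmp$bin[cmp$comparison == "map-shuffle"], "large")
  expect_error(compare_modalities(list(map = mk(1))), "2 seeds")
})
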