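test_that("synthetic connectomes are symmetric, mirrored and reproducible", {
  c1 <- make_connectome(12, n_modules = 2, seed = 4)
  c2 <- make_connectome(12, n_modules = 2, seed = 4)
  c3 <- make_connectome(12, n_modules = 2, seed = 5)
  expect_identical(c1$weights, c2$weights)
  expect_false(identical(c1$weights, c3$weights))
  W <- c1$weights
  expect_equal(W, t(W))
  expect_true(all(W >= 0))
  expect_equal(diag(W), rep(0, 12))
  # hemispheric mirror: w(i, j) = w(partner(i), partner(j))
  p <- c1$regions$homotopic_partner
  expect_equal(W, W[p, p])
  # homotopic entries all equal (the common homotopic weight, scaled)
  hom <- W[cbind(1:6, 7:12)]
  expect_equal(hom, rep(hom[1], 6))
  expect_error(make_connectome(13), "even")
  expect_error(make_connectome(12, n_modules = 10), "n_modules")
})

test_that("unscaled connectome honours the homotopic weight and density", {
  c4 <- make_connectome(4, n_modules = 1, homotopic_weight = 0.5, seed = 1,
                        spectral_gain = NULL)
  expect_equal(c4$weights[1, 3], 0.5)
  expect_equal(c4$weights[2, 4], 0.5)
  c90 <- make_connectome(90, density = 0.3, seed = 2, spectral_gain = NULL)
  W <- c90$weights
  offdiag <- W[upper.tri(W)]
  hom_idx <- upper.tri(W) & (row(W) == col(W) - 45)
  frac <- mean(W[upper.tri(W) & !hom_idx] > 0)
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("synthetic maps are positive, mirrored, mean-1 and correlated", {
  rt <- make_region_table(90)
  m <- make_maps(rt, spatial_correlation = 0.3, seed = 2)
  for (map in m) {
    expect_true(all(map$values > 0))
    expect_lt(abs(mean(map$values) - 1), 1e-10)
    expect_equal(map$values[1:45], map$values[46:90])
  }
  expect_lt(abs(cor(m$ach$values, m$na$values) - 0.3), 0.15)
  m0 <- make_maps(rt, spatial_correlation = 0, seed = 3)
  expect_lt(abs(cor(m0$ach$values, m0$na$values)), 0.15)
  m1 <- make_maps(rt, spatial_correlation = 1, seed = 4)
  expect_equal(m1$ach$values, m1$na$values)
})

test_that("stage datasets carry exact ground truth and subject structure", {
  conn <- tiny_connectome()
  cfg <- tiny_config()
  out <- simulate_stage_dataset(conn, n_subjects = 2, subject_noise_sd = 0,
                                config = cfg, seed = 6)
  expect_length(out$datasets, 8)  # 2 subjects x 4 stages
  # zero subject noise: every subject shares the stage parameters
  gt <- out$ground_truth
  expect_equal(unname(gt$subject_params$sub01_N3),
               unname(gt$subject_params$sub02_N3))
  expect_equal(unname(gt$subject_params$sub01_N3),
               unname(gt$stage_params$N3))
  # determinism
  out2 <- simulate_stage_dataset(conn, n_subjects = 2, subject_noise_sd = 0,
                                 config = cfg, seed = 6)
  expect_identical(out$datasets[[3]]$series, out2$datasets[[3]]$series)
  # jitter recorded exactly
  out3 <- simulate_stage_dataset(conn, n_subjects = 3,
                                 subject_noise_sd = 0.05, config = cfg,
                                 seed = 7)
  gt3 <- out3$ground_truth
  expect_equal(unname(gt3$subject_params$sub02_W),
               unname(gt3$stage_params$W + gt3$subject_jitter[2, ]))
})

test_that("higher coupling offsets raise functional connectivity", {
  conn <- make_connectome(16, n_modules = 2, seed = 3)
  # transient long enough that shared homeostatic relaxation cannot
  # masquerade as connectivity in the weakly coupled condition
  cfg <- desk_sim_config(t_transient = 250, t_main = 120)
  pars <- list(W = c(0, 0), N1 = c(0.2, 0), N2 = c(0, 0), N3 = c(0, 0))
  mean_fc <- function(stage, seeds) {
    vals <- vapply(seeds, function(s) {
      out <- simulate_stage_dataset(conn, stage_params = pars,
                                    n_subjects = 1, subject_noise_sd = 0,
                                    config = cfg, seed = s)
      ds <- Filter(function(d) d$stage == stage, out$datasets)[[1]]
      mean(lower_triangle_vector(compute_fc(ds$series)))
    }, numeric(1))
    mean(vals)
  }
  seeds <- 1:5
  expect_gt(mean_fc("N1", seeds), mean_fc("W", seeds))
})

test_that("nucleus signals follow the map weighting", {
  set.seed(10)
  s <- matrix(rnorm(6 * 500), 6)
  uni <- make_nucleus_series(s, rep(1, 6), noise_sd = 0)
  expect_equal(uni, colMeans(s), tolerance = 1e-12)
  w <- c(10, 1, 1, 1, 1, 0.1)
  sig <- make_nucleus_series(s, w, noise_sd = 0)
  expect_gt(cor(sig, s[1, ]), cor(sig, s[6, ]))
  s1 <- make_nucleus_series(s, w, noise_sd = 0.5, seed = 3)
  s2 <- make_nucleus_series(s, w, noise_sd = 0.5, seed = 3)
  expect_identical(s1, s2)
  expect_error(make_nucleus_series(s, w[-1]), "does not match")
})
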