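test_that("sigmoid matches its closed form and bounds", {
  expect_equal(sigmoid(1, mu = 1, sigma = 4), 0.5)
  expect_equal(sigmoid(5, mu = 1, sigma = 4), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(sigmoid(-1e4, 1, 4), 0)
  expect_equal(sigmoid(1e4, 1, 4), 1)
  x <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(sigmoid(x, 1, 4)) > 0))
  expect_error(sigmoid(0, 1, 0), "positive")
  expect_error(sim_config(sigma_E = -1), "positive")
})

test_that("plasticity derivative vanishes exactly at the set point", {
  cfg <- sim_config()
  conn <- tiny_connectome()
  n <- 8
  d <- wc_derivatives(rep(cfg$rho_E, n), runif(n), runif(n), cfg, conn)
  expect_equal(d$da_IE, rep(0, n))
})

test_that("with zero coupling each node's derivatives are autonomous", {
  cfg <- sim_config(G = 0)
  conn <- tiny_connectome()
  set.seed(1)
  E <- runif(8); I <- runif(8); a <- runif(8)
  d1 <- wc_derivatives(E, I, a, cfg, conn)
  E2 <- E; E2[-1] <- runif(7)  # perturb all other nodes
  d2 <- wc_derivatives(E2, I, a, cfg, conn)
  expect_equal(d1$dE[1], d2$dE[1])
  expect_equal(d1$dI[1], d2$dI[1])
})

test_that("single-node equilibrium matches the root-finder oracle", {
  cfg <- sim_config(G = 0, D = 0)
  eq <- single_node_oracle(cfg)
  d <- wc_derivatives(eq["E"], eq["I"], eq["a_IE"], cfg,
                      matrix(0, 1, 1))
  expect_lt(max(abs(c(d$dE, d$dI, d$da_IE))), 1e-8)
})

test_that("integrator converges to the oracle equilibrium without noise", {
  # the plasticity weight travels tens of units with a ~20 s effective
  # time constant, so convergence to 1e-6 needs a long fast transient
  cfg <- desk_sim_config(G = 0, D = 0, t_transient = 500, t_main = 2)
  eq <- single_node_oracle(cfg)
  # 2-node zero connectome (region tables need pairs)
  conn <- connectome(matrix(0, 2, 2))
  tr <- simulate_wc(conn, cfg, seed = 1, record_I = TRUE, record_a = TRUE)
  last <- ncol(tr$E)
  expect_lt(abs(tr$E[1, last] - eq["E"]), 1e-6)
  expect_lt(abs(tr$I[1, last] - eq["I"]), 1e-6)
  expect_lt(abs(tr$a_IE[1, last] - eq["a_IE"]), 1e-6)
})

test_that("trajectories are bitwise reproducible per seed", {
  cfg <- tiny_config()
  conn <- tiny_connectome()
  t1 <- simulate_wc(conn, cfg, seed = 7)
  t2 <- simulate_wc(conn, cfg, seed = 7)
  t3 <- simulate_wc(conn, cfg, seed = 8)
  expect_identical(t1$E, t2$E)
  expect_false(identical(t1$E, t3$E))
})

test_that("uncoupled nodes have near-zero cross-correlations", {
  # long transient: raw (unfiltered) traces are compared, so the shared
  # homeostatic relaxation must have fully died out
  cfg <- desk_sim_config(G = 0, t_transient = 250, t_main = 120)
  conn <- tiny_connectome(n = 6)
  cc <- numeric(0)
  for (s in 1:3) {
    tr <- simulate_wc(conn, cfg, seed = s)
    fc <- cor(t(tr$E))
    cc <- c(cc, abs(fc[lower.tri(fc)]))
  }
  expect_lt(mean(cc), 0.1)
})

test_that("homeostasis holds the per-node mean near the set point", {
  cfg <- desk_sim_config()
  conn <- tiny_connectome(n = 10, seed = 3)
  sim <- simulate_bold(conn, cfg, seed = 2, band = NULL)
  expect_true(all(abs(sim$e_mean - cfg$rho_E) < 0.02))
})

test_that("attractor is insensitive to the initial conditions", {
  conn <- tiny_connectome(n = 6)
  cfgA <- desk_sim_config(t_main = 30)
  cfgB <- desk_sim_config(t_main = 30, init_E = 0.4, init_I = 0.3,
                          init_a_IE = 5)
  a <- simulate_bold(conn, cfgA, seed = 4, band = NULL)
  b <- simulate_bold(conn, cfgB, seed = 4, band = NULL)
  expect_lt(max(abs(a$e_mean - b$e_mean)), 1e-3)
})
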