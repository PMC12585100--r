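test_that("FC is the pairwise Pearson correlation with unit diagonal", {
  x <- rnorm(50)
  s <- rbind(x, x, -x)
  fc <- compute_fc(s)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(diag(fc), rep(1, 3))
  set.seed(4)
  w <- rbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(compute_fc(w)[1, 2]), 0.1)
  expect_error(compute_fc(rbind(x, rep(1, 50))), "region 2")
  expect_error(compute_fc(matrix(rnorm(4), 2, 2)), "3 time points")
})

test_that("FC is invariant to positive affine rescaling of rows", {
  set.seed(8)
  s <- matrix(rnorm(200), 4)
  fc1 <- compute_fc(s)
  fc2 <- compute_fc(s * c(2, 0.5, 10, 1) + c(-3, 0, 5, 100))
  expect_equal(fc1, fc2, tolerance = 1e-12)
})

test_that("lower-triangle vectorization has the documented order and length", {
  m <- matrix(0, 3, 3)
  m[lower.tri(m)] <- c(21, 31, 32)  # column-major fill: (2,1),(3,1),(3,2)
  m <- m + t(m)
  expect_equal(lower_triangle_vector(m), c(21, 31, 32))  # row-major i > j
  expect_equal(length(lower_triangle_vector(diag(90))), 4005)
  # round-trip: vector + diagonal reconstructs a symmetric matrix
  v <- lower_triangle_vector(m)
  r <- matrix(0, 3, 3); r[lower.tri(r)] <- c(v[1], v[2], v[3])
  expect_equal(r + t(r), m)
})

test_that("euccorrelation trades off distance and correlation", {
  expect_equal(euccorrelation(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euccorrelation(c(1, 2, 3), c(2, 4, 6)), sqrt(14),
               tolerance = 1e-12)
  # anti-correlated pair: |rho| = 1, plain Euclidean distance
  v <- c(1, 2, 3); w <- c(3, 2, 1)
  expect_equal(euccorrelation(v, w), sqrt(sum((v - w)^2)))
  # symmetric, and never below the Euclidean distance
  set.seed(1)
  for (k in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    e <- euccorrelation(a, b)
    expect_equal(e, euccorrelation(b, a))
    expect_gte(e, sqrt(sum((a - b)^2)))
  }
  expect_error(euccorrelation(1:4, 1:5), "lengths")
  expect_error(euccorrelation(rep(1, 5), rep(2, 5)), "constant")
  # orthogonal vectors -> infinite (never selected by an argmin)
  expect_equal(euccorrelation(c(1, -1, 1, -1), c(1, 1, -1, -1)), Inf)
})

test_that("nodal strength sums incoming FC and is permutation-equivariant", {
  fc <- matrix(0.5, 5, 5); diag(fc) <- 1
  expect_equal(nodal_strength(fc), rep(2, 5))
  expect_equal(nodal_strength(diag(4)), rep(0, 4))
  m <- random_corr(6, seed = 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  P <- diag(6)[perm, ]
  expect_equal(nodal_strength(P %*% m %*% t(P)),
               nodal_strength(m)[perm])
})

test_that("confound regression leaves an orthogonal residual", {
  set.seed(3)
  cfd <- rnorm(200)
  y <- 2 * cfd + 3
  expect_lt(max(abs(regress_confound(y, cfd))), 1e-10)
  z <- rnorm(200)
  r <- regress_confound(z, cfd)
  expect_lt(abs(cor(r, cfd)), 1e-10)
  # orthogonal target: residual is just the demeaned target
  zo <- unname(residuals(lm(z ~ cfd))) + 5  # orthogonal by construction
  expect_equal(regress_confound(zo, cfd), zo - mean(zo), tolerance = 1e-8)
  expect_error(regress_confound(z, rep(1, 200)), "degenerate")
})

test_that("nucleus FC correlates one signal against every region", {
  set.seed(5)
  s <- matrix(rnorm(4000), 4)
  v <- nucleus_fc(s[2, ], s)
  expect_equal(v[2], 1)
  expect_true(all(abs(v[-2]) < 0.1))
  expect_error(nucleus_fc(rnorm(10), s), "time lengths")
})

test_that("group FC averaging is element-wise with optional Fisher z", {
  a <- random_corr(4, 1); b <- random_corr(4, 2)
  g <- group_mean_fc(list(a, b))
  expect_equal(g[2, 1], mean(c(a[2, 1], b[2, 1])))
  gz <- group_mean_fc(list(a, b), fisher_z = TRUE)
  expect_equal(gz[2, 1], tanh(mean(atanh(c(a[2, 1], b[2, 1])))))
})
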