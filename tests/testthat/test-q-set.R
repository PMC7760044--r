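test_that("the parameterisation has one free parameter per layer block and is exact at zero", {
  d2 <- function_to_distribution(fx_and2())
  qp2 <- q_parameterization(d2)
  expect_equal(qp2$n_params, 2L)   # (N-1)^2 per z-layer, N = 2
  d3 <- function_to_distribution(fx_xor3())
  qp3 <- q_parameterization(d3)
  expect_equal(qp3$n_params, 12L)  # 4 per layer for N = 3
  # zero parameter vector returns the base bit-identically
  expect_identical(q_distribution(qp3, rep(0, 12)), d3)
  # any parameter vector preserves both source-target marginals
  set.seed(1)
  for (i in 1:20) {
    th <- rnorm(12) * 0.01
    q <- try(q_distribution(qp3, th), silent = TRUE)
    if (inherits(q, "try-error")) next
    expect_lt(infodelta:::.marginal_deviation(d3, q), 1e-12)
  }
})

test_that("feasible intervals of the binary AND tensor match the closed form", {
  qp <- q_parameterization(function_to_distribution(fx_and2()))
  expect_equal(feasible_interval(qp, 1), c(0, 1 / 4))
  expect_equal(feasible_interval(qp, 2), c(0, 0))   # second layer pinned
  expect_error(feasible_interval(qp, 3), "index")
  # strictly interior tensor: slack on both sides of every parameter
  d <- fx_random_dist(c(2, 2, 2), seed = 11, concentration = 5)
  qp <- q_parameterization(d)
  for (j in 1:2) {
    iv <- feasible_interval(qp, j)
    expect_lt(iv[1], 0)
    expect_gt(iv[2], 0)
  }
})

test_that("Q samples are deterministic, feasible and include the base point", {
  d <- function_to_distribution(fx_and2())
  qp <- q_parameterization(d)
  s1 <- sample_q(qp, 100, seed = 5)
  s2 <- sample_q(qp, 100, seed = 5)
  expect_identical(s1$theta, s2$theta)
  expect_equal(s1$theta[1, ], c(0, 0))
  # AND: the pinned second layer leaves only the alpha direction
  expect_true(all(abs(s1$theta[, 2]) < 1e-12))
  expect_true(all(s1$theta[, 1] >= -1e-12 & s1$theta[, 1] <= 0.25 + 1e-12))
  for (i in seq_len(100))
    expect_lt(infodelta:::.marginal_deviation(d, s1$distributions[[i]]),
              1e-12)
})

test_that("within Q only the source-pair entropies vary (marginal constancy)", {
  set.seed(33)
  tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
  d <- function_to_distribution(discrete_function(tab))
  qs <- sample_q(q_parameterization(d), 200, seed = 7)
  sp0 <- shannon_profile(d)
  consts <- c("HX", "HY", "HZ", "HXZ", "HYZ")
  for (q in qs$distributions) {
    sp <- shannon_profile(q)
    for (f in consts) expect_lt(abs(sp[[f]] - sp0[[f]]), 1e-10)
  }
})

test_that("sampled Q clouds are low-dimensional: a curve for N=2 functions, a plane for N=3", {
  # Every binary function's Q maps onto a one-dimensional manifold in
  # delta space: either the feasible polytope itself is (at most) one
  # dimensional, or the delta image collapses onto a line. (The image of
  # the AND family is a curved arc, so its centred cloud has two nonzero
  # singular values; one-dimensionality there comes from the single free
  # parameter.)
  for (f in enumerate_functions(2)) {
    d <- function_to_distribution(f)
    if (shannon_profile(d)$omega < 1e-12) next
    qp <- q_parameterization(d)
    free <- sum(vapply(1:2, function(j) diff(feasible_interval(qp, j)), 1)
                > 1e-12)
    if (free <= 1L) succeed() else {
      qs <- sample_q(qp, 200, seed = 9)
      cl <- as.matrix(qs$deltas[, c("deltaX", "deltaY", "deltaZ")])
      cl <- cl[stats::complete.cases(cl), , drop = FALSE]
      sv <- svd(scale(cl, center = TRUE, scale = FALSE))$d
      expect_lte(sum(sv > 1e-7), 1)
    }
  }
  # N = 3: rank at most 2 (the cloud lies in a plane)
  set.seed(61)
  tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
  d3 <- function_to_distribution(discrete_function(tab))
  qs3 <- sample_q(q_parameterization(d3), 500, seed = 13)
  cl3 <- as.matrix(qs3$deltas[, c("deltaX", "deltaY", "deltaZ")])
  cl3 <- cl3[stats::complete.cases(cl3), ]
  sv3 <- svd(scale(cl3, center = TRUE, scale = FALSE))$d
  expect_lte(sum(sv3 > 1e-7), 2)
})

test_that("the Q plane contains the delta image of Q and the shared line", {
  set.seed(77)
  for (rep in 1:3) {
    tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
    d <- function_to_distribution(discrete_function(tab))
    if (shannon_profile(d)$omega < 1e-6) next
    pl <- q_plane(d)
    qs <- sample_q(q_parameterization(d), 300, seed = 17 + rep)
    dd <- qs$deltas[stats::complete.cases(qs$deltas), ]
    res <- abs(pl$coef_dxy * (dd$deltaX - dd$deltaY) +
                 pl$coef_dz * (1 - dd$deltaZ))
    expect_lt(max(res), 1e-8)
    # the line deltaX = deltaY, deltaZ = 1 always satisfies the equation
    for (t in c(-1, 0, 0.4, 2))
      expect_equal(plane_residual(pl, c(t, t, 1)), 0)
  }
  # symmetric distribution with c2 = c3 but c1 != c4: reduces to dX = dY
  dsym <- function_to_distribution(fx_and2())
  pl <- q_plane(dsym)
  expect_equal(pl$c2, pl$c3, tolerance = 1e-12)
  expect_true(abs(pl$coef_dxy) > 1e-12)
  expect_equal(plane_residual(pl, c(0.3, 0.3, 0.7)), 0, tolerance = 1e-12)
  expect_gt(abs(plane_residual(pl, c(0.3, 0.5, 0.7))), 1e-12)
  # fully symmetric ternary XOR: both coefficients vanish (vacuous form)
  expect_true(q_plane(function_to_distribution(fx_xor3()))$degenerate)
})
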