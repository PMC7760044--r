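test_that("corner-case functions have the expected optimisation PID", {
  # ternary Z = X: all information unique to X
  s <- pid_broja(function_to_distribution(fx_zx3()))
  expect_equal(c(s$UX, s$UY, s$R, s$S), c(log2(3), 0, 0, 0),
               tolerance = 1e-6)
  # ternary XOR: pure synergy
  s <- pid_broja(function_to_distribution(fx_xor3()))
  expect_equal(c(s$UX, s$UY, s$R, s$S), c(0, 0, 0, log2(3)),
               tolerance = 1e-6)
  # binary AND: R = I(Z:X) since UX = 0, and S = 1/2 bit
  s <- pid_broja(function_to_distribution(fx_and2()))
  d <- function_to_distribution(fx_and2())
  expect_equal(s$R, shannon_profile(d)$IZ_X, tolerance = 1e-6)
  expect_equal(c(s$UX, s$UY, s$S), c(0, 0, 0.5), tolerance = 1e-6)
})

test_that("objective profile evaluates the four objectives and polices Q membership", {
  d <- function_to_distribution(fx_xor3())
  sp <- shannon_profile(d)
  prof <- objective_profile(d, d)
  expect_equal(unname(prof["IZX_given_Y"]), log2(3), tolerance = 1e-12)
  expect_equal(unname(prof["CI"]), sp$CI, tolerance = 1e-12)
  expect_equal(unname(prof["IZ_XY"]), sp$IZ_XY, tolerance = 1e-12)
  # AND at the alpha = 1/4 extreme: co-information strictly larger than at base
  dand <- function_to_distribution(fx_and2())
  qp <- q_parameterization(dand)
  qext <- q_distribution(qp, c(0.25, 0))
  expect_gt(objective_profile(dand, qext)["CI"],
            objective_profile(dand, dand)["CI"])
  # non-member rejected
  other <- joint_distribution(array(1 / 8, c(2, 2, 2)))
  expect_error(objective_profile(dand, other), "not in Q")
})

test_that("the conditional-MI difference is invariant over Q (optimiser sanity identity)", {
  set.seed(19)
  for (rep in 1:5) {
    tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
    d <- function_to_distribution(discrete_function(tab))
    sp0 <- shannon_profile(d)
    qs <- sample_q(q_parameterization(d), 100, seed = rep)
    for (q in qs$distributions[seq(1, 100, by = 10)]) {
      sp <- shannon_profile(q)
      lhs <- (sp$HXY + sp$HYZ - sp$HY - sp$HXYZ) -
        (sp$HXY + sp$HXZ - sp$HX - sp$HXYZ)
      expect_equal(lhs, sp0$IZ_X - sp0$IZ_Y, tolerance = 1e-10)
    }
  }
})

test_that("solver matches the exhaustive binary grid oracle on all 16 functions", {
  for (f in enumerate_functions(2)) {
    d <- function_to_distribution(f)
    if (shannon_profile(d)$omega < 1e-12) next
    got <- pid_broja(d, n_starts = 3)
    want <- grid_oracle_n2(d)
    expect_equal(got$UX, max(want$UX, 0), tolerance = 2e-3)
    expect_equal(got$UY, max(want$UY, 0), tolerance = 2e-3)
    expect_equal(got$R, max(want$R, 0), tolerance = 2e-3)
    expect_equal(got$S, max(want$S, 0), tolerance = 2e-3)
  }
})

test_that("solver matches the independent Frank-Wolfe/HiGHS reference on random ternary functions", {
  set.seed(271)
  for (rep in 1:5) {
    tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
    d <- function_to_distribution(discrete_function(tab))
    if (shannon_profile(d)$omega < 1e-12) next
    got <- pid_broja(d, n_starts = 3)
    ref <- python_broja_oracle(d)
    expect_equal(got$UX, max(ref$UX, 0), tolerance = 2e-3)
    expect_equal(got$UY, max(ref$UY, 0), tolerance = 2e-3)
    expect_equal(got$R, max(ref$R, 0), tolerance = 2e-3)
    expect_equal(got$S, max(ref$S, 0), tolerance = 2e-3)
  }
})

test_that("the four optima are mutually consistent with the decomposition system", {
  set.seed(83)
  for (rep in 1:5) {
    tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
    d <- function_to_distribution(discrete_function(tab))
    sp <- shannon_profile(d)
    s <- pid_broja(d, n_starts = 3)
    expect_lt(abs(s$UX + s$R - sp$IZ_X), 1e-6)
    expect_lt(abs(s$UY + s$R - sp$IZ_Y), 1e-6)
    expect_lt(abs(s$UX + s$UY + s$R + s$S - sp$IZ_XY), 1e-6)
    expect_lt(abs((s$UX - s$UY) - (sp$IZ_X - sp$IZ_Y)), 1e-6)
    # S - R equals the interaction information of the data (solver-agnostic)
    expect_lt(abs((s$S - s$R) - sp$II), 1e-6)
    expect_gte(min(s$UX, s$UY, s$R, s$S), 0)
  }
})
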