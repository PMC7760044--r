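test_that("count normalisation reproduces known tensors and rejects bad input", {
  # two equal counts -> half/half
  ct <- count_table(c(0, 1), c(0, 1), c(0, 1), c(1, 1))
  d <- normalize_counts(ct, c(2, 2, 2))
  expect_equal(unclass(d)[1, 1, 1], 0.5)
  expect_equal(unclass(d)[2, 2, 2], 0.5)
  expect_equal(sum(unclass(d)), 1)

  # the redundant-with-error counts give the printed 2x2x2 tensor
  ct <- count_table(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1),
                    z = c(0, 0, 1, 1), count = c(3, 1, 1, 3))
  d <- normalize_counts(ct, c(2, 2, 2))
  expect_equal(unclass(d), unclass(fx_rdnerr()))

  # degenerate and malformed inputs
  expect_error(normalize_counts(count_table(0, 0, 0, 0)), "total count")
  expect_error(normalize_counts(count_table(0, 0, 5, 1), c(2, 2, 2)),
               "out of range")
  expect_error(count_table(0, 0, 0, -1), "nonnegative")
  expect_error(joint_distribution(array(1 / 4, c(2, 2, 2))), "sum to 1")
})

test_that("entropies match hand values and a brute-force oracle", {
  # fair coin marginal
  p <- array(0, c(2, 2, 2)); p[1, 1, 1] <- p[2, 1, 1] <- 0.5
  expect_equal(entropy(joint_distribution(p), "X"), 1.0)
  # point mass
  p <- array(0, c(2, 2, 2)); p[1, 1, 1] <- 1
  expect_equal(entropy(joint_distribution(p), "XYZ"), 0.0)
  # ternary XOR: 9 equiprobable events
  d <- function_to_distribution(fx_xor3())
  expect_equal(entropy(d, "XYZ"), 2 * log2(3), tolerance = 1e-12)
  expect_error(entropy(d, character()), "at least one")

  # random tensors against the enumeration oracle
  for (s in 1:8) {
    ns <- sample(2:4, 3, replace = TRUE)
    d <- fx_random_dist(ns, seed = 100 + s)
    for (sub in list("X", "Z", c("X", "Y"), c("Y", "Z"), c("X", "Y", "Z"))) {
      dims <- match(sub, c("X", "Y", "Z"))
      expect_equal(entropy(d, sub), brute_entropy(d, dims), tolerance = 1e-10)
    }
  }
})

test_that("mutual information behaves on independent, functional and conditional cases", {
  # independent bits
  d <- joint_distribution(array(1 / 8, c(2, 2, 2)))
  expect_equal(mutual_information(d, "X", "Y"), 0, tolerance = 1e-12)
  # ternary Z = X: I(Z:X) = log2 3
  d <- function_to_distribution(fx_zx3())
  expect_equal(mutual_information(d, "Z", "X"), log2(3), tolerance = 1e-12)
  # ternary XOR: I(X:Y|Z) = log2 3
  d <- function_to_distribution(fx_xor3())
  expect_equal(mutual_information(d, "X", "Y", given = "Z"), log2(3),
               tolerance = 1e-12)
  expect_error(mutual_information(d, "X", c("X", "Y")), "disjoint")
})

test_that("shannon_profile matches the inclusion-exclusion oracle on random tensors", {
  for (s in 1:25) {
    ns <- sample(2:4, 3, replace = TRUE)
    d <- fx_random_dist(ns, seed = 300 + s)
    sp <- shannon_profile(d)
    bp <- brute_profile(d)
    for (f in names(bp))
      expect_equal(sp[[f]], bp[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("co-information is minus the interaction information and entropies are monotone", {
  # independent triple: everything vanishes
  d <- joint_distribution(array(1 / 8, c(2, 2, 2)))
  sp <- shannon_profile(d)
  expect_equal(sp$II, 0, tolerance = 1e-12)
  expect_equal(sp$omega, 0, tolerance = 1e-12)
  # binary XOR: II = +1 bit
  sp <- shannon_profile(function_to_distribution(fx_xor2()))
  expect_equal(sp$II, 1, tolerance = 1e-12)
  # RdnErr: II = S - R = -(1 - H(1/4))
  sp <- shannon_profile(fx_rdnerr())
  expect_equal(sp$II, -(1 - (-0.75 * log2(0.75) - 0.25 * log2(0.25))),
               tolerance = 1e-12)

  for (s in 1:1000) {
    d <- fx_random_dist(c(2, 3, 2), seed = 5000 + s)
    sp <- shannon_profile(d)
    expect_equal(sp$CI, -sp$II, tolerance = 1e-12)
    expect_gte(sp$HXY, sp$HX - 1e-12)
    expect_gte(sp$IZ_X, -1e-12)
    expect_gte(sp$IZ_Y, -1e-12)
    expect_gte(sp$IX_Y, -1e-12)
    expect_gte(sp$IZ_XY, -1e-12)
  }
})
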