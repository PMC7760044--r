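test_that("function enumeration is complete, ordered and guarded", {
  f2 <- enumerate_functions(2)
  expect_length(f2, 16)
  expect_equal(unclass(f2[[1]]), matrix(0L, 2, 2), ignore_attr = TRUE)
  # base-N counting: the second function flips only the last cell
  expect_equal(sum(unclass(f2[[2]])), 1L)
  tabs <- vapply(f2, function(f) paste(unclass(f), collapse = ""), "")
  expect_false(anyDuplicated(tabs) > 0)
  expect_error(enumerate_functions(1), "at least 2")
  expect_error(enumerate_functions(4), "exhaustive_override")
})

test_that("function distributions carry the input weights onto the graph of f", {
  d <- function_to_distribution(fx_and2())
  expect_equal(unclass(d)[1, 1, 1], 1 / 4)
  expect_equal(unclass(d)[2, 2, 2], 1 / 4)
  expect_equal(sum(unclass(d) > 0), 4L)
  # ternary XOR: 9 cells of 1/9 at z = (x + y) mod 3
  d <- function_to_distribution(fx_xor3())
  for (x in 0:2) for (y in 0:2)
    expect_equal(unclass(d)[x + 1, y + 1, (x + y) %% 3 + 1], 1 / 9)
  # point-mass input: degenerate joint with omega = 0
  w <- matrix(0, 2, 2); w[1, 1] <- 1
  d <- function_to_distribution(fx_and2(), w)
  expect_equal(shannon_profile(d)$omega, 0, tolerance = 1e-12)
  expect_error(function_to_distribution(fx_and2(), matrix(1, 2, 2)),
               "probability matrix")
})

test_that("the binary atlas reproduces the exact-arithmetic family structure", {
  # Exact symbolic enumeration of all 16 binary functions (rational
  # probabilities, entropies in the basis {1, log2 3}) yields 4 distinct
  # non-degenerate delta points and 2 degenerate constant functions.
  atlas <- build_atlas(2)
  expect_equal(nrow(atlas$entries), 16L)
  expect_equal(nrow(atlas$families), 4L)
  expect_length(atlas$degenerate, 2L)
  # the known points: the two pairwise corners, the XOR top corner and the
  # AND-like interior family
  fam <- atlas$families
  key <- apply(round(fam[, c("deltaX", "deltaY", "deltaZ")], 6), 1, paste,
               collapse = ",")
  expect_true(all(c("0,1,0", "1,0,0", "1,1,1") %in% key))
  and_d <- info_deltas(function_to_distribution(fx_and2()))
  expect_true(any(abs(fam$deltaX - and_d$deltaX) < 1e-9 &
                    abs(fam$deltaZ - and_d$deltaZ) < 1e-9))
  # member counts cover the function space
  expect_equal(sum(fam$n_members) + length(atlas$degenerate), 16L)
})

test_that("swapping the sources transposes the delta coordinates", {
  set.seed(42)
  for (i in 1:100) {
    tab <- matrix(sample(0:2, 9, TRUE), 3, 3)
    d1 <- function_to_distribution(discrete_function(tab))
    d2 <- function_to_distribution(discrete_function(t(tab)))
    if (shannon_profile(d1)$omega < 1e-12) next
    c1 <- info_deltas(d1); c2 <- info_deltas(d2)
    expect_equal(c1$deltaX, c2$deltaY, tolerance = 1e-10)
    expect_equal(c1$deltaY, c2$deltaX, tolerance = 1e-10)
    expect_equal(c1$deltaZ, c2$deltaZ, tolerance = 1e-10)
  }
})

test_that("atlas builds are deterministic and families well separated", {
  a1 <- build_atlas(2)
  a2 <- build_atlas(2)
  expect_identical(a1$entries, a2$entries)
  expect_identical(a1$families, a2$families)
  atlas <- get_atlas3()
  fam <- atlas$families[, c("deltaX", "deltaY", "deltaZ")]
  dmat <- as.matrix(stats::dist(fam))
  diag(dmat) <- Inf
  # distinct delta points are separated far above the grouping tolerance
  expect_gt(min(dmat), 1e-4)
  expect_equal(sum(atlas$families$n_members) + length(atlas$degenerate),
               19683L)
})

test_that("atlas representatives are the lexicographically smallest members", {
  atlas <- build_atlas(2)
  for (fid in atlas$families$family_id) {
    members <- atlas$entries$table[!is.na(atlas$entries$family_id) &
                                     atlas$entries$family_id == fid]
    rep_tab <- paste(unclass(family_representative(atlas, fid)),
                     collapse = "")
    expect_equal(rep_tab, min(members))
  }
  expect_error(family_representative(atlas, 999), "unknown family")
})
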