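test_that("a binary library has one entry per non-degenerate family with coherent records", {
  lib <- build_function_library(2, samples_per_family = 40, seed = 3)
  expect_length(lib$entries, 4L)   # the exact-arithmetic family count
  for (e in lib$entries) {
    # base delta point is cloud point 1
    expect_equal(unname(e$delta), unname(e$cloud[1, ]), tolerance = 1e-12)
    # every cloud point satisfies the family's Q-plane equation
    cl <- e$cloud[stats::complete.cases(e$cloud), , drop = FALSE]
    res <- e$plane$coef_dxy * (cl[, 1] - cl[, 2]) +
      e$plane$coef_dz * (1 - cl[, 3])
    expect_lt(max(abs(res)), 1e-8)
    # both solvers stored and consistent with the sum rule
    d <- function_to_distribution(e$representative)
    sp <- shannon_profile(d)
    expect_lt(abs(e$pid_broja$UX + e$pid_broja$UY + e$pid_broja$R +
                    e$pid_broja$S - sp$IZ_XY), 1e-6)
    expect_lt(abs(e$pid_ppid$UX + e$pid_ppid$UY + e$pid_ppid$R +
                    e$pid_ppid$S - sp$IZ_XY), 1e-12)
  }
  # deterministic rebuild
  lib2 <- build_function_library(2, samples_per_family = 40, seed = 3)
  expect_equal(lib$entries[[2]]$cloud, lib2$entries[[2]]$cloud)
  # single-sample cloud contains exactly the base point
  lib1 <- build_function_library(2, samples_per_family = 1, seed = 3)
  expect_equal(nrow(lib1$entries[[1]]$cloud), 1L)
})

test_that("queries self-match library points and rank families sensibly", {
  lib <- build_function_library(2, samples_per_family = 40, seed = 3)
  # querying each family's own base point returns it at distance 0
  for (e in lib$entries) {
    qr <- query_function_library(lib, e$delta, k = 2)
    expect_equal(qr$family_id[1], e$family_id)
    expect_lt(qr$distance[1], 1e-12)
  }
  # round-trip for sampled cloud points
  for (e in lib$entries) {
    cl <- e$cloud[stats::complete.cases(e$cloud), , drop = FALSE]
    for (i in seq_len(min(10, nrow(cl)))) {
      qr <- query_function_library(lib, cl[i, ], k = 1)
      expect_equal(qr$family_id[1], e$family_id)
    }
  }
  expect_error(query_function_library(lib, c(0.1, NA, 0.2)), "finite")
})

test_that("library archives round-trip through JSON + TSV", {
  lib <- build_function_library(2, samples_per_family = 25, seed = 8)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_function_library(lib, jp, tp)
  lib2 <- read_function_library(jp, tp)
  expect_equal(length(lib2$entries), length(lib$entries))
  for (i in seq_along(lib$entries)) {
    a <- lib$entries[[i]]; b <- lib2$entries[[i]]
    expect_equal(unname(b$delta), unname(a$delta), tolerance = 1e-12)
    expect_equal(unclass(b$representative), unclass(a$representative),
                 ignore_attr = TRUE)
    expect_equal(b$cloud, a$cloud, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(b$pid_broja$R, a$pid_broja$R, tolerance = 1e-12)
    expect_equal(b$pid_ppid$UY, a$pid_ppid$UY, tolerance = 1e-12)
  }
  # a query against the restored library gives identical ranking
  q1 <- query_function_library(lib, c(0.6, 0.6, 0.25), k = 3)
  q2 <- query_function_library(lib2, c(0.6, 0.6, 0.25), k = 3)
  expect_equal(q1$family_id, q2$family_id)
  expect_equal(q1$distance, q2$distance, tolerance = 1e-12)
  unlink(c(jp, tp))
})

test_that("synthetic data from a binary function is matched to its own family", {
  lib <- build_function_library(2, samples_per_family = 40, seed = 3)
  and_delta <- info_deltas(function_to_distribution(fx_and2()))
  and_fid <- query_function_library(lib, and_delta, k = 1)$family_id[1]
  ct <- generate_observations(generator_config(fx_and2(), n = 5000,
                                               noise = 0.03, seed = 31))
  emp <- info_deltas(normalize_counts(ct, c(2, 2, 2)))
  qr <- query_function_library(lib, emp, k = 1)
  expect_equal(qr$family_id[1], and_fid)
})
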