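# Shared fixtures and independent oracles for the test suite. All fixtures
# are built in code; heavyweight shared computations are cached per session.

# --- canonical distributions -------------------------------------------------

# "redundant with error": X always equals Z, Y errs with probability 1/4
fx_rdnerr <- function() {
  p <- array(0, c(2, 2, 2))
  p[1, 1, 1] <- 3 / 8; p[1, 2, 1] <- 1 / 8
  p[2, 1, 2] <- 1 / 8; p[2, 2, 2] <- 3 / 8
  joint_distribution(p)
}

fx_and2 <- function() discrete_function(matrix(c(0, 0, 0, 1), 2, 2))
fx_xor2 <- function() discrete_function(matrix(c(0, 1, 1, 0), 2, 2))
fx_xor3 <- function()
  discrete_function(matrix(c(0, 1, 2, 1, 2, 0, 2, 0, 1), 3, 3))
fx_zx3 <- function() discrete_function(matrix(rep(0:2, 3), 3, 3))   # Z = X

fx_random_dist <- function(ns, seed, concentration = 1)
  random_distribution(ns, concentration = concentration, seed = seed)

# --- brute-force Shannon oracle ---------------------------------------------

# Entropy of an arbitrary variable subset by direct enumeration of events
# (independent of the package's marginalisation code path).
brute_entropy <- function(dist, dims) {
  v <- unclass(dist)
  ns <- dim(v)
  ev <- expand.grid(x = seq_len(ns[1]), y = seq_len(ns[2]),
                    z = seq_len(ns[3]))
  p <- mapply(function(x, y, z) v[x, y, z], ev$x, ev$y, ev$z)
  key <- do.call(paste, ev[, dims, drop = FALSE])
  m <- tapply(p, key, sum)
  m <- m[m > 1e-15]
  -sum(m * log2(m))
}

# Full profile via the inclusion-exclusion definitions.
brute_profile <- function(dist) {
  H <- function(d) brute_entropy(dist, d)
  hx <- H(1); hy <- H(2); hz <- H(3)
  hxy <- H(c(1, 2)); hxz <- H(c(1, 3)); hyz <- H(c(2, 3))
  hxyz <- H(1:3)
  ci <- hx + hy + hz - hxy - hxz - hyz + hxyz
  list(HX = hx, HY = hy, HZ = hz, HXY = hxy, HXZ = hxz, HYZ = hyz,
       HXYZ = hxyz, CI = ci, II = -ci, omega = hx + hy + hz - hxyz,
       IZ_X = hx + hz - hxz, IZ_Y = hy + hz - hyz,
       IX_Y = hx + hy - hxy, IZ_XY = hxy + hz - hxyz)
}

# --- independent solvers for the optimisation PID ---------------------------

# Exact vectorised grid search over the 2-parameter Q set of an N = 2
# distribution: evaluates the four objectives on every feasible (alpha,
# beta) grid point.
grid_oracle_n2 <- function(dist, step = 1 / 400) {
  stopifnot(all(attr(dist, "alphabet_sizes") == 2L))
  v <- as.vector(unclass(dist))   # cells (x,y,z) with x fastest
  grid <- seq(-1, 1, by = step)
  ab <- expand.grid(alpha = grid, beta = grid)
  # layer deltas: alpha adds (+,-,-,+) to layer 1, beta likewise to layer 2
  q <- matrix(rep(v, each = nrow(ab)), nrow(ab), 8)
  sgn <- c(1, -1, -1, 1)
  for (j in 1:4) q[, j] <- q[, j] + sgn[j] * ab$alpha
  for (j in 5:8) q[, j] <- q[, j] + sgn[j - 4] * ab$beta
  ok <- rowSums(q < -1e-12 | q > 1 + 1e-12) == 0
  q <- q[ok, , drop = FALSE]
  xlx <- function(m) ifelse(m > 1e-15, m * log2(m), 0)
  Hrow <- function(m) -rowSums(xlx(m))
  HXYZ <- Hrow(q)
  HXY <- Hrow(cbind(q[, 1] + q[, 5], q[, 2] + q[, 6],
                    q[, 3] + q[, 7], q[, 4] + q[, 8]))
  HXZ <- Hrow(cbind(q[, 1] + q[, 3], q[, 2] + q[, 4],
                    q[, 5] + q[, 7], q[, 6] + q[, 8]))
  HYZ <- Hrow(cbind(q[, 1] + q[, 2], q[, 3] + q[, 4],
                    q[, 5] + q[, 6], q[, 7] + q[, 8]))
  HX <- Hrow(cbind(q[, 1] + q[, 3] + q[, 5] + q[, 7],
                   q[, 2] + q[, 4] + q[, 6] + q[, 8]))
  HY <- Hrow(cbind(q[, 1] + q[, 2] + q[, 5] + q[, 6],
                   q[, 3] + q[, 4] + q[, 7] + q[, 8]))
  HZ <- Hrow(cbind(q[, 1] + q[, 2] + q[, 3] + q[, 4],
                   q[, 5] + q[, 6] + q[, 7] + q[, 8]))
  sp0 <- shannon_profile(dist)
  list(UX = min(HXY + HYZ - HY - HXYZ),
       UY = min(HXY + HXZ - HX - HXYZ),
       R = max(HX + HY + HZ - HXY - HXZ - HYZ + HXYZ),
       S = sp0$IZ_XY - min(HXY + HZ - HXYZ))
}

# Frank-Wolfe + HiGHS reference solver in Python/scipy (independent
# language, parameterisation and algorithm); see broja-oracle.py.
python_broja_oracle <- function(dist, iters = 3000) {
  script <- testthat::test_path("broja-oracle.py")
  inp <- jsonlite::toJSON(
    list(p = as.vector(unclass(dist)),
         shape = attr(dist, "alphabet_sizes"), iters = iters),
    auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2("python", script, input = as.character(inp), stdout = TRUE,
            stderr = FALSE))
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# --- cached heavyweight shared objects --------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Atlas for N = 3 with uniform i.i.d. inputs.
get_atlas3 <- function() cached("atlas3", build_atlas(3))

# Function library for N = 3 (shared by the pipeline-recovery and
# decomposition-structure checks); modest cloud size keeps the suite fast.
get_library3 <- function()
  cached("library3",
         build_function_library(3, samples_per_family = 120, seed = 97L,
                                broja_starts = 2L))
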