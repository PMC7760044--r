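# Seeded generators for empirical-style data with the statistical structure
# the analysis assumes: a discrete function driving the target, optional
# output noise, and optional source coupling emulating linkage
# disequilibrium between loci.

#' Configuration for the synthetic observation generator
#'
#' @param f a [discrete_function()] generating the target.
#' @param n number of observations (>= 1).
#' @param noise probability \eqn{\epsilon \in [0, 1]} that the output symbol
#'   is replaced by a uniform random symbol (fraction of corrupted
#'   outputs).
#' @param coupling mixture weight \eqn{\rho \in [0, 1]} of a
#'   diagonal-concentrated source distribution: the sources are drawn from
#'   \eqn{(1-\rho)\,\mathrm{uniform}(N^2) + \rho\,\mathrm{uniform}}
#'   on the diagonal \eqn{x = y}, emulating linkage-disequilibrium-like
#'   dependence between the sources.
#' @param seed integer seed; the generator is deterministic per seed.
#' @return A list of class \code{"generator_config"}.
#' @export
generator_config <- function(f, n, noise = 0, coupling = 0, seed = 1L) {
  stopifnot(inherits(f, "discrete_function"))
  n <- as.integer(n)
  if (n < 1L) .stopf("n must be at least 1")
  if (noise < 0 || noise > 1) .stopf("noise must be in [0, 1]")
  if (coupling < 0 || coupling > 1) .stopf("coupling must be in [0, 1]")
  structure(list(f = f, n = n, noise = noise, coupling = coupling,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw synthetic observations of a noisy discrete function
#'
#' Samples source pairs from the (possibly coupled) input distribution,
#' applies the function \eqn{z = f(x, y)}, and corrupts each output with
#' probability \code{noise} by a uniform symbol. Deterministic per seed.
#'
#' @param cfg a [generator_config()].
#' @return A [count_table()] of the sampled triples.
#' @examples
#' xor3 <- discrete_function(matrix(c(0, 1, 2, 1, 2, 0, 2, 0, 1), 3, 3))
#' ct <- generate_observations(generator_config(xor3, n = 1000, seed = 42))
#' sum(ct$count)
#' @export
generate_observations <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  N <- attr(cfg$f, "N")
  tab <- unclass(cfg$f)
  with_preserved_seed(cfg$seed, {
    on_diag <- stats::runif(cfg$n) < cfg$coupling
    x <- integer(cfg$n); y <- integer(cfg$n)
    nd <- sum(on_diag)
    if (nd > 0L) {
      d <- sample.int(N, nd, replace = TRUE) - 1L
      x[on_diag] <- d; y[on_diag] <- d
    }
    nu <- cfg$n - nd
    if (nu > 0L) {
      x[!on_diag] <- sample.int(N, nu, replace = TRUE) - 1L
      y[!on_diag] <- sample.int(N, nu, replace = TRUE) - 1L
    }
    z <- tab[cbind(x + 1L, y + 1L)]
    corrupt <- stats::runif(cfg$n) < cfg$noise
    if (any(corrupt))
      z[corrupt] <- sample.int(N, sum(corrupt), replace = TRUE) - 1L
    agg <- stats::aggregate(list(count = rep(1L, cfg$n)),
                            by = list(x = x, y = y, z = z), FUN = sum)
    count_table(agg$x, agg$y, agg$z, agg$count)
  })
}

#' Random joint distribution from a symmetric Dirichlet
#'
#' Draws a dense probability tensor whose cells follow a symmetric
#' Dirichlet distribution; large concentrations approach the uniform
#' tensor. Used for test fixtures and property checks.
#'
#' @param alphabet_sizes integer vector \code{c(Nx, Ny, Nz)}.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed optional integer seed.
#' @return A [joint_distribution()].
#' @export
random_distribution <- function(alphabet_sizes, concentration = 1,
                                seed = NULL) {
  alphabet_sizes <- as.integer(alphabet_sizes)
  if (concentration <= 0) .stopf("concentration must be positive")
  ncells <- prod(alphabet_sizes)
  with_preserved_seed(seed, {
    g <- stats::rgamma(ncells, shape = concentration, rate = 1)
    while (sum(g) <= 0) g <- stats::rgamma(ncells, concentration, 1)
    joint_distribution(array(g / sum(g), alphabet_sizes), alphabet_sizes)
  })
}
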