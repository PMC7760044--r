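#' Parameterise the marginal-preserving set Q of a distribution
#'
#' Q is the set of all joint distributions q(x, y, z) sharing the (X, Z) and
#' (Y, Z) marginals of a base distribution; only the dependence between the
#' sources is allowed to vary. Within each z-layer of the tensor the
#' permissible perturbations form a linear family: free adjustments on the
#' leading (Nx-1) x (Ny-1) block, with the last column and row taking the
#' negated block row/column sums and the corner taking the total, so that
#' every row and column sum of the layer -- and hence both marginals -- is
#' preserved exactly. The feasible region is the polytope where all tensor
#' entries remain in [0, 1].
#'
#' @param dist a [joint_distribution()] (the base distribution).
#' @return An object of class \code{"q_param"}: a list with the base
#'   distribution, the number of free parameters \code{n_params}, the
#'   \code{index} data frame (z, x, y cell of each free parameter) and the
#'   effect matrix \code{A} (cells x parameters) such that a parameter
#'   vector \eqn{\theta} represents the tensor \eqn{vec(p) + A\theta}.
#' @examples
#' and2 <- discrete_function(matrix(c(0, 0, 0, 1), 2, 2))
#' qp <- q_parameterization(function_to_distribution(and2))
#' qp$n_params # one free parameter per z-layer for N = 2
#' @export
q_parameterization <- function(dist) {
  stopifnot(inherits(dist, "joint_distribution"))
  ns <- attr(dist, "alphabet_sizes")
  nx <- ns[1]; ny <- ns[2]; nz <- ns[3]
  if (nx < 2L || ny < 2L)
    .stopf("source alphabets must have at least 2 symbols to perturb")
  ncells <- nx * ny * nz
  cell <- function(x, y, z) x + nx * (y - 1L) + nx * ny * (z - 1L)
  idx <- expand.grid(x = seq_len(nx - 1L), y = seq_len(ny - 1L),
                     z = seq_len(nz))[, c("z", "x", "y")]
  idx <- idx[order(idx$z, idx$x, idx$y), ]
  rownames(idx) <- NULL
  np <- nrow(idx)
  A <- matrix(0, ncells, np)
  for (j in seq_len(np)) {
    x <- idx$x[j]; y <- idx$y[j]; z <- idx$z[j]
    A[cell(x, y, z), j] <- 1
    A[cell(x, ny, z), j] <- -1
    A[cell(nx, y, z), j] <- -1
    A[cell(nx, ny, z), j] <- 1
  }
  structure(list(base = dist, alphabet_sizes = ns, n_params = np,
                 index = idx, A = A),
            class = "q_param")
}

#' @export
print.q_param <- function(x, ...) {
  ns <- x$alphabet_sizes
  cat(sprintf("<q_param> base %dx%dx%d, %d free parameters (%d per z-layer)\n",
              ns[1], ns[2], ns[3], x$n_params, x$n_params / ns[3]))
  invisible(x)
}

#' Distribution represented by a parameter vector
#'
#' @param param a [q_parameterization()].
#' @param theta numeric parameter vector (length \code{param$n_params}).
#' @return A [joint_distribution()]. The zero vector returns the base
#'   distribution unchanged.
#' @export
q_distribution <- function(param, theta) {
  stopifnot(inherits(param, "q_param"))
  theta <- as.numeric(theta)
  if (length(theta) != param$n_params)
    .stopf("theta must have length %d", param$n_params)
  if (all(theta == 0)) return(param$base)
  v <- as.vector(param$base) + as.vector(param$A %*% theta)
  if (any(v < -1e-9) || any(v > 1 + 1e-9))
    .stopf("theta leaves the feasible polytope (entry outside [0, 1])")
  v[v < 0] <- 0
  joint_distribution(array(v, param$alphabet_sizes), param$alphabet_sizes)
}

# Max absolute deviation of the (X,Z) and (Y,Z) marginals of q from base.
.marginal_deviation <- function(base, q) {
  max(abs(apply(unclass(q), c(1, 3), sum) - apply(unclass(base), c(1, 3), sum)),
      abs(apply(unclass(q), c(2, 3), sum) - apply(unclass(base), c(2, 3), sum)))
}

#' Closed-form feasible interval of one Q parameter
#'
#' With all other parameters held at zero, the set of values of parameter
#' \code{index} keeping every tensor entry in [0, 1] is a closed interval,
#' computed exactly from the box constraints. For the binary AND
#' distribution the first-layer parameter has interval [0, 1/4] while the
#' second-layer parameter is pinned to [0, 0].
#'
#' @param param a [q_parameterization()].
#' @param index parameter index in \code{1:param$n_params}.
#' @return Numeric \code{c(lo, hi)}.
#' @export
feasible_interval <- function(param, index) {
  stopifnot(inherits(param, "q_param"))
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > param$n_params)
    .stopf("index must be in 1..%d", param$n_params)
  .segment_interval(as.vector(param$base), param$A[, index])
}

# Feasible t-range for moving along direction dv from point p (cells stay
# in [0, 1]).
.segment_interval <- function(p, dv) {
  lo <- -Inf; hi <- Inf
  pos <- dv > 1e-14; neg <- dv < -1e-14
  if (any(pos)) {
    lo <- max(lo, max(-p[pos] / dv[pos]))
    hi <- min(hi, min((1 - p[pos]) / dv[pos]))
  }
  if (any(neg)) {
    lo <- max(lo, max((1 - p[neg]) / dv[neg]))
    hi <- min(hi, min(-p[neg] / dv[neg]))
  }
  # snap floating dust to exact bounds
  if (abs(lo) < 1e-15) lo <- 0
  if (abs(hi) < 1e-15) hi <- 0
  if (lo > hi) { m <- (lo + hi) / 2; lo <- hi <- m }
  c(lo, hi)
}

#' Sample member distributions of Q
#'
#' Draws feasible parameter vectors by seeded rejection sampling from the
#' product of per-parameter feasible intervals, then refines each accepted
#' point with hit-and-run sweeps (uniform steps along random directions
#' inside the polytope) for interior coverage. Sample 1 is always the base
#' distribution itself. If box rejection accepts fewer than 0.1% of draws,
#' sampling falls back to single-axis jitter from the base point, which is
#' feasible by construction.
#'
#' @param param a [q_parameterization()].
#' @param n_samples number of samples (>= 1), including the base.
#' @param seed integer seed; fixed seed gives identical samples.
#' @param sweeps hit-and-run sweeps per sample (default 10).
#' @return An object of class \code{"q_sample"}: list with \code{theta}
#'   (n x n_params matrix), \code{deltas} (data frame of delta coordinates
#'   and omega per sample; NA where omega vanishes), \code{distributions}
#'   (list of [joint_distribution()]), \code{param} and \code{seed}.
#' @export
sample_q <- function(param, n_samples, seed = 1L, sweeps = 10L) {
  stopifnot(inherits(param, "q_param"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) .stopf("n_samples must be at least 1")
  np <- param$n_params
  base_vec <- as.vector(param$base)
  A <- param$A
  box <- vapply(seq_len(np), function(j) feasible_interval(param, j),
                numeric(2))
  widths <- box[2, ] - box[1, ]
  theta <- matrix(0, n_samples, np)
  with_preserved_seed(seed, {
    accepted <- 1L; tries <- 0L; fallback <- FALSE
    while (accepted < n_samples) {
      if (!fallback) {
        cand <- box[1, ] + stats::runif(np) * widths
        tries <- tries + 1L
        ok <- {
          v <- base_vec + as.vector(A %*% cand)
          all(v >= -1e-15) && all(v <= 1 + 1e-15)
        }
        if (ok) {
          accepted <- accepted + 1L
          theta[accepted, ] <- cand
        } else if (tries > 1000L && (accepted - 1) / tries < 0.001) {
          fallback <- TRUE
        }
      } else {
        j <- sample.int(np, 1L)
        cand <- numeric(np)
        cand[j] <- stats::runif(1, box[1, j], box[2, j])
        accepted <- accepted + 1L
        theta[accepted, ] <- cand
      }
    }
    # hit-and-run refinement for interior coverage
    free <- widths > 1e-14
    if (any(free)) {
      for (i in seq(2L, length.out = max(0L, n_samples - 1L))) {
        th <- theta[i, ]
        p <- base_vec + as.vector(A %*% th)
        for (s in seq_len(sweeps)) {
          u <- numeric(np)
          u[free] <- stats::rnorm(sum(free))
          nu <- sqrt(sum(u^2))
          if (nu < 1e-12) next
          u <- u / nu
          dv <- as.vector(A %*% u)
          seg <- .segment_interval(p, dv)
          if (seg[2] - seg[1] < 1e-14) next
          t <- stats::runif(1, seg[1], seg[2])
          th <- th + t * u
          p <- p + t * dv
        }
        theta[i, ] <- th
      }
    }
  })
  dists <- vector("list", n_samples)
  dd <- data.frame(sample = seq_len(n_samples), deltaX = NA_real_,
                   deltaY = NA_real_, deltaZ = NA_real_, omega = NA_real_)
  for (i in seq_len(n_samples)) {
    q <- q_distribution(param, theta[i, ])
    if (.marginal_deviation(param$base, q) > 1e-12)
      .stopf("internal error: sampled distribution left Q")
    dists[[i]] <- q
    sp <- shannon_profile(q)
    dd$omega[i] <- sp$omega
    if (sp$omega >= 1e-12) {
      d <- info_deltas(q)
      dd$deltaX[i] <- d$deltaX; dd$deltaY[i] <- d$deltaY
      dd$deltaZ[i] <- d$deltaZ
    }
  }
  structure(list(theta = theta, deltas = dd, distributions = dists,
                 param = param, seed = as.integer(seed)),
            class = "q_sample")
}

#' @export
print.q_sample <- function(x, ...) {
  cat(sprintf("<q_sample> %d samples of Q (seed %d), %d parameters\n",
              nrow(x$theta), x$seed, ncol(x$theta)))
  invisible(x)
}

#' Export a Q sample as a TSV table
#'
#' @param qs a [sample_q()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_q_sample_tsv <- function(qs, path) {
  stopifnot(inherits(qs, "q_sample"))
  th <- as.data.frame(qs$theta)
  names(th) <- paste0("param_", seq_len(ncol(th)))
  utils::write.table(cbind(sample = qs$deltas$sample, th,
                           qs$deltas[, c("deltaX", "deltaY", "deltaZ")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The plane in delta space containing the image of Q
#'
#' Within a Q set only H(XY) and H(XYZ) vary; the entropies H(X), H(Y),
#' H(Z), H(XZ) and H(YZ) are fixed by the preserved marginals. Collecting
#' the constant combinations
#' \eqn{c_1 = H_X + H_Y + H_Z}, \eqn{c_2 = -H_X + H_{XZ}},
#' \eqn{c_3 = -H_Y + H_{YZ}}, \eqn{c_4 = -H_Z + H_{XZ} + H_{YZ}},
#' every member of Q satisfies
#' \deqn{(c_1 - c_4)(\delta_X - \delta_Y) + (c_3 - c_2)(1 - \delta_Z) = 0,}
#' a plane that always contains the line \eqn{\delta_X = \delta_Y,
#' \delta_Z = 1}.
#'
#' @param dist a [joint_distribution()] (any member of the Q set).
#' @return An object of class \code{"q_plane"}: list with \code{c1..c4}, the
#'   plane coefficients \code{coef_dxy} \eqn{= c_1 - c_4} and
#'   \code{coef_dz} \eqn{= c_3 - c_2}, and \code{degenerate} (TRUE when both
#'   coefficients vanish and the constraint is vacuous).
#' @export
q_plane <- function(dist) {
  stopifnot(inherits(dist, "joint_distribution"))
  sp <- shannon_profile(dist)
  c1 <- sp$HX + sp$HY + sp$HZ
  c2 <- -sp$HX + sp$HXZ
  c3 <- -sp$HY + sp$HYZ
  c4 <- -sp$HZ + sp$HXZ + sp$HYZ
  a <- c1 - c4; b <- c3 - c2
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 coef_dxy = a, coef_dz = b,
                 degenerate = abs(a) < 1e-12 && abs(b) < 1e-12),
            class = "q_plane")
}

#' @export
print.q_plane <- function(x, digits = 4, ...) {
  cat(sprintf("<q_plane> %.*f (dX - dY) + %.*f (1 - dZ) = 0%s\n",
              digits, x$coef_dxy, digits, x$coef_dz,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Residual of a delta point against a Q plane
#'
#' @param plane a [q_plane()].
#' @param delta a \code{"delta_coords"} object, or a numeric vector
#'   \code{c(deltaX, deltaY, deltaZ)}.
#' @return The signed residual of the plane equation (0 on the plane).
#' @export
plane_residual <- function(plane, delta) {
  stopifnot(inherits(plane, "q_plane"))
  if (inherits(delta, "delta_coords"))
    delta <- c(delta$deltaX, delta$deltaY, delta$deltaZ)
  plane$coef_dxy * (delta[1] - delta[2]) + plane$coef_dz * (1 - delta[3])
}
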