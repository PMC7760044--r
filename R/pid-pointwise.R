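# Pointwise PID (Finn-Lizier): specificity/ambiguity decomposition of the
# pointwise mutual information, with redundancy from per-event minima.

#' Pointwise information terms of every positive-probability event
#'
#' For each event \eqn{(x, y, z)} with \eqn{p > 0} and each source
#' \eqn{a \in \{x, y\}}, the pointwise mutual information
#' \eqn{i(a:z) = \log_2 p(a|z)/p(a)} splits into two nonnegative parts:
#' the specificity \eqn{i^+ = h(a) = -\log_2 p(a)} and the ambiguity
#' \eqn{i^- = h(a|z) = -\log_2 p(a|z)}, with \eqn{i = i^+ - i^-}. The
#' probability-weighted sum of \eqn{i} over events recovers the mutual
#' information \eqn{I(a : Z)}.
#'
#' @param dist a [joint_distribution()].
#' @return A data frame of class \code{"pointwise_terms"}: one row per
#'   positive-probability event with columns \code{x, y, z, p},
#'   \code{iX_plus, iX_minus, iX}, \code{iY_plus, iY_minus, iY}.
#' @export
pointwise_terms <- function(dist) {
  stopifnot(inherits(dist, "joint_distribution"))
  v <- unclass(dist)
  ns <- attr(dist, "alphabet_sizes")
  px <- as.vector(apply(v, 1, sum))
  py <- as.vector(apply(v, 2, sum))
  pz <- as.vector(apply(v, 3, sum))
  pxz <- apply(v, c(1, 3), sum)
  pyz <- apply(v, c(2, 3), sum)
  ev <- which(v > .zero_tol, arr.ind = TRUE)
  colnames(ev) <- c("x", "y", "z")
  out <- data.frame(x = ev[, "x"] - 1L, y = ev[, "y"] - 1L,
                    z = ev[, "z"] - 1L, p = v[ev])
  iXp <- -log2(px[ev[, "x"]])
  iYp <- -log2(py[ev[, "y"]])
  iXm <- -log2(pxz[cbind(ev[, "x"], ev[, "z"])] / pz[ev[, "z"]])
  iYm <- -log2(pyz[cbind(ev[, "y"], ev[, "z"])] / pz[ev[, "z"]])
  out$iX_plus <- iXp; out$iX_minus <- iXm; out$iX <- iXp - iXm
  out$iY_plus <- iYp; out$iY_minus <- iYm; out$iY <- iYp - iYm
  class(out) <- c("pointwise_terms", "data.frame")
  out
}

#' Pointwise redundancy from specificity/ambiguity minima
#'
#' The pointwise redundancy takes, for every positive-probability event,
#' the minimum specificity across the sources and, separately, the minimum
#' ambiguity across the sources:
#' \deqn{r^+_{min} = E[\min_a i^+(a \to z)], \quad
#'       r^-_{min} = E[\min_a i^-(a \to z)], \quad
#'       R = r^+_{min} - r^-_{min}.}
#'
#' @param dist a [joint_distribution()].
#' @return Named list with \code{rmin_plus}, \code{rmin_minus} and \code{R}
#'   (bits).
#' @export
ppid_redundancy <- function(dist) {
  pt <- pointwise_terms(dist)
  rmin_plus <- sum(pt$p * pmin(pt$iX_plus, pt$iY_plus))
  rmin_minus <- sum(pt$p * pmin(pt$iX_minus, pt$iY_minus))
  list(rmin_plus = rmin_plus, rmin_minus = rmin_minus,
       R = rmin_plus - rmin_minus)
}

#' Pointwise partial information decomposition
#'
#' Computes the redundancy by [ppid_redundancy()] and completes the
#' decomposition through the defining system
#' \eqn{U_X = I(Z:X) - R}, \eqn{U_Y = I(Z:Y) - R},
#' \eqn{S = I(Z:XY) - U_X - U_Y - R}. Components are not clamped: negative
#' values are meaningful and indicate misinformation (a source that on
#' average misleads about the target).
#'
#' @param dist a [joint_distribution()].
#' @return An object of class \code{"pid"} with fields \code{UX, UY, R, S}
#'   (bits, possibly negative), \code{rmin_plus}, \code{rmin_minus} and
#'   \code{solver = "ppid"}.
#' @examples
#' # "redundant with error": X always equals Z, Y errs with probability 1/4
#' p <- array(0, c(2, 2, 2))
#' p[1, 1, 1] <- 3 / 8; p[1, 2, 1] <- 1 / 8
#' p[2, 1, 2] <- 1 / 8; p[2, 2, 2] <- 3 / 8
#' pid_ppid(joint_distribution(p)) # (R, UX, UY, S) = (1, 0, -0.81, 0.81)
#' @export
pid_ppid <- function(dist) {
  stopifnot(inherits(dist, "joint_distribution"))
  red <- ppid_redundancy(dist)
  sp <- shannon_profile(dist)
  UX <- sp$IZ_X - red$R
  UY <- sp$IZ_Y - red$R
  S <- sp$IZ_XY - UX - UY - red$R
  structure(list(UX = UX, UY = UY, R = red$R, S = S,
                 rmin_plus = red$rmin_plus, rmin_minus = red$rmin_minus,
                 solver = "ppid"),
            class = "pid")
}
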