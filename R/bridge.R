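# Identities linking delta coordinates to PID components. These hold for
# ANY decomposition satisfying the defining system, so they are computed
# from the distribution's deltas alone and serve as solver-agnostic
# cross-checks.

#' Synergy-minus-redundancy from delta coordinates
#'
#' \eqn{S - R = \tfrac{\Omega}{2}(\delta_X + \delta_Y + \delta_Z - 1)},
#' which equals the interaction information \eqn{II(X, Y, Z)} of the
#' distribution: the synergy/redundancy balance grows with distance from
#' the origin of delta space.
#'
#' @param delta a \code{"delta_coords"} object.
#' @return \eqn{S - R} in bits.
#' @export
s_minus_r <- function(delta) {
  stopifnot(inherits(delta, "delta_coords"))
  delta$omega / 2 * (delta$deltaX + delta$deltaY + delta$deltaZ - 1)
}

#' Unique-information difference from delta coordinates
#'
#' \eqn{U_X - U_Y = \Omega(\delta_Y - \delta_X)}: the distance from the
#' \eqn{\delta_X = \delta_Y} diagonal measures the imbalance of unique
#' information between the sources.
#'
#' @param delta a \code{"delta_coords"} object.
#' @return \eqn{U_X - U_Y} in bits.
#' @export
ux_minus_uy <- function(delta) {
  stopifnot(inherits(delta, "delta_coords"))
  delta$omega * (delta$deltaY - delta$deltaX)
}

#' Consistency of a PID solution with the delta-space identities
#'
#' Checks a set of PID components against the identities that any solution
#' must satisfy for its source distribution, with all delta-side quantities
#' computed from the distribution alone (never from the solver output), so
#' the check is a genuine cross-validation:
#' three rows linking the mutual informations to component sums
#' (\eqn{\tfrac{\Omega}{2}(\delta_X+\delta_Y-\delta_Z+1) = U_X+U_Y+R+S} and
#' the two single-source rows), the synergy-redundancy identity
#' ([s_minus_r()] versus \eqn{S - R}), the unique-difference identity
#' ([ux_minus_uy()] versus \eqn{U_X - U_Y}), and the off-plane form
#' \eqn{\tfrac{\Omega}{2}(2 - d) = U_X+U_Y+R+S} with \eqn{d} the
#' [plane_distance()].
#'
#' @param pid a \code{"pid"} object (any solver).
#' @param dist the [joint_distribution()] the components refer to.
#' @param tol pass/fail tolerance in bits (default 1e-6).
#' @return A data frame of class \code{"consistency_report"} with one row
#'   per identity: name, residual (bits) and pass flag.
#' @export
check_consistency <- function(pid, dist, tol = 1e-6) {
  stopifnot(inherits(pid, "pid"), inherits(dist, "joint_distribution"))
  d <- info_deltas(dist)
  om <- d$omega
  total <- pid$UX + pid$UY + pid$R + pid$S
  resid <- c(
    mi_joint = om / 2 * (d$deltaX + d$deltaY - d$deltaZ + 1) - total,
    mi_x = om / 2 * (-d$deltaX + d$deltaY - d$deltaZ + 1) -
      (pid$R + pid$UX),
    mi_y = om / 2 * (d$deltaX - d$deltaY - d$deltaZ + 1) -
      (pid$R + pid$UY),
    synergy_redundancy = s_minus_r(d) - (pid$S - pid$R),
    unique_difference = ux_minus_uy(d) - (pid$UX - pid$UY),
    off_plane = om / 2 * (2 - plane_distance(d)) - total)
  out <- data.frame(identity = names(resid), residual = unname(resid),
                    pass = abs(unname(resid)) <= tol)
  class(out) <- c("consistency_report", "data.frame")
  attr(out, "tol") <- tol
  out
}
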