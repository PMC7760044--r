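#' Normalised information-delta coordinates
#'
#' The raw delta of a variable is the change in co-information when that
#' variable joins the set, e.g. \eqn{\Delta_Z = CI(X,Y,Z) - CI(X,Y) =
#' -I(X:Y|Z)}. Normalising by the multi-information \eqn{\Omega} gives the
#' delta coordinates \eqn{\delta_\bullet = -\Delta_\bullet / \Omega}, each a
#' conditional mutual information over \eqn{\Omega} and hence nonnegative:
#' \deqn{\delta_X = I(Y:Z|X)/\Omega,\quad \delta_Y = I(X:Z|Y)/\Omega,\quad
#'       \delta_Z = I(X:Y|Z)/\Omega.}
#'
#' The coordinates are undefined when all three variables are independent
#' (\eqn{\Omega = 0}); an error is raised for \eqn{\Omega < 10^{-12}} bits
#' and a warning for \eqn{\Omega < 10^{-6}} bits, where the ratios become
#' ill-conditioned.
#'
#' @param dist a [joint_distribution()].
#' @return An object of class \code{"delta_coords"}: a list with
#'   \code{deltaX, deltaY, deltaZ} (dimensionless), \code{rawDeltaX,
#'   rawDeltaY, rawDeltaZ} (bits, the unnormalised deltas) and \code{omega}
#'   (bits).
#' @examples
#' # ternary XOR: Z = (X + Y) mod 3 with uniform i.i.d. inputs
#' f <- discrete_function(matrix(c(0, 1, 2, 1, 2, 0, 2, 0, 1), 3, 3))
#' info_deltas(function_to_distribution(f)) # (1, 1, 1)
#' @export
info_deltas <- function(dist) {
  stopifnot(inherits(dist, "joint_distribution"))
  sp <- shannon_profile(dist)
  omega <- sp$omega
  if (omega < 1e-12)
    .stopf(paste0("delta coordinates are undefined: the variables are ",
                  "(numerically) independent (omega = %.3g bits)"), omega)
  if (omega < 1e-6)
    warning(sprintf(
      "omega = %.3g bits is very small; delta coordinates are ill-conditioned",
      omega), call. = FALSE)
  # conditional MIs, numerically stabler than the alternating entropy sums
  iYZgX <- sp$HXY + sp$HXZ - sp$HX - sp$HXYZ
  iXZgY <- sp$HXY + sp$HYZ - sp$HY - sp$HXYZ
  iXYgZ <- sp$HXZ + sp$HYZ - sp$HZ - sp$HXYZ
  d <- list(deltaX = iYZgX / omega,
            deltaY = iXZgY / omega,
            deltaZ = iXYgZ / omega,
            rawDeltaX = -iYZgX,
            rawDeltaY = -iXZgY,
            rawDeltaZ = -iXYgZ,
            omega = omega)
  # cross-check against the four-entropy form of the same quantities
  alt <- c((-sp$HX + sp$HXY + sp$HXZ - sp$HXYZ) / omega,
           (-sp$HY + sp$HXY + sp$HYZ - sp$HXYZ) / omega,
           (-sp$HZ + sp$HXZ + sp$HYZ - sp$HXYZ) / omega)
  if (max(abs(alt - c(d$deltaX, d$deltaY, d$deltaZ))) > 1e-10)
    .stopf("internal inconsistency between the two delta formulations")
  structure(d, class = "delta_coords")
}

# Build a delta_coords object directly from known numbers (used by the
# atlas fast path and by tests).
.delta_coords <- function(dx, dy, dz, omega) {
  structure(list(deltaX = dx, deltaY = dy, deltaZ = dz,
                 rawDeltaX = -dx * omega, rawDeltaY = -dy * omega,
                 rawDeltaZ = -dz * omega, omega = omega),
            class = "delta_coords")
}

#' @export
print.delta_coords <- function(x, digits = 4, ...) {
  cat(sprintf("<delta_coords> delta = (%.*f, %.*f, %.*f), omega = %.*f bits\n",
              digits, x$deltaX, digits, x$deltaY, digits, x$deltaZ,
              digits, x$omega))
  invisible(x)
}

#' Signed distance from the function plane
#'
#' All distributions generated by a discrete function \eqn{Z = f(X, Y)} with
#' independent sources lie on the plane \eqn{\delta_Z = \delta_X + \delta_Y
#' - 1}. This returns the signed off-plane coordinate
#' \eqn{d = \delta_Z - \delta_X - \delta_Y + 1}, zero for on-plane points.
#'
#' @param delta a \code{"delta_coords"} object.
#' @return The signed plane distance (dimensionless).
#' @export
plane_distance <- function(delta) {
  stopifnot(inherits(delta, "delta_coords"))
  delta$deltaZ - delta$deltaX - delta$deltaY + 1
}

#' Mutual informations recovered from delta coordinates
#'
#' The delta coordinates and \eqn{\Omega} determine the three mutual
#' informations involving the target:
#' \deqn{I(Z:XY) = \tfrac{\Omega}{2}(\delta_X + \delta_Y - \delta_Z + 1)}
#' \deqn{I(Z:X)  = \tfrac{\Omega}{2}(-\delta_X + \delta_Y - \delta_Z + 1)}
#' \deqn{I(Z:Y)  = \tfrac{\Omega}{2}(\delta_X - \delta_Y - \delta_Z + 1)}
#'
#' @param delta a \code{"delta_coords"} object.
#' @return Named numeric vector \code{c(IZ_XY, IZ_X, IZ_Y)} in bits.
#' @export
mi_from_deltas <- function(delta) {
  stopifnot(inherits(delta, "delta_coords"))
  om <- delta$omega
  dx <- delta$deltaX; dy <- delta$deltaY; dz <- delta$deltaZ
  c(IZ_XY = om / 2 * (dx + dy - dz + 1),
    IZ_X  = om / 2 * (-dx + dy - dz + 1),
    IZ_Y  = om / 2 * (dx - dy - dz + 1))
}
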