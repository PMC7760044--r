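#' Joint distribution of a discrete variable triple
#'
#' Constructs the basic data object of the package: a dense three-way
#' probability tensor \eqn{p(x, y, z)} over two source variables X, Y and a
#' target variable Z, each taking values in a finite 0-based alphabet.
#'
#' @param values numeric 3-dimensional array of probabilities, indexed
#'   \code{[x, y, z]} with 1-based array indices corresponding to 0-based
#'   symbols.
#' @param alphabet_sizes integer vector of length 3 \code{c(Nx, Ny, Nz)};
#'   defaults to \code{dim(values)}.
#' @param normalize if \code{TRUE}, rescale \code{values} to sum to one
#'   (useful when passing raw weights); if \code{FALSE} (default) the input
#'   must already be normalised to within \code{1e-12}.
#'
#' @return An object of class \code{"joint_distribution"}: the probability
#'   array with an \code{alphabet_sizes} attribute.
#' @examples
#' p <- array(0, c(2, 2, 2))
#' p[1, 1, 1] <- p[2, 2, 2] <- 0.5 # Z = X = Y, uniform
#' d <- joint_distribution(p)
#' entropy(d, "Z")
#' @export
joint_distribution <- function(values, alphabet_sizes = dim(values),
                               normalize = FALSE) {
  if (!is.numeric(values) || length(dim(values)) != 3L)
    .stopf("`values` must be a numeric 3-dimensional array")
  alphabet_sizes <- as.integer(alphabet_sizes)
  if (length(alphabet_sizes) != 3L || any(alphabet_sizes < 1L))
    .stopf("`alphabet_sizes` must be three positive integers")
  if (!identical(dim(values), alphabet_sizes))
    .stopf("tensor shape (%s) does not match alphabet_sizes (%s)",
           paste(dim(values), collapse = "x"),
           paste(alphabet_sizes, collapse = "x"))
  if (any(values < -1e-15))
    .stopf("probabilities must be nonnegative (min = %.3g)", min(values))
  values[values < 0] <- 0
  tot <- sum(values)
  if (normalize) {
    if (tot <= 0) .stopf("cannot normalise an all-zero tensor")
    values <- values / tot
  } else if (abs(tot - 1) > 1e-12) {
    .stopf("probabilities must sum to 1 (got %.15g); use normalize = TRUE",
           tot)
  }
  structure(values,
            alphabet_sizes = alphabet_sizes,
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  ns <- attr(x, "alphabet_sizes")
  cat(sprintf("<joint_distribution> alphabet %d x %d x %d (X, Y, Z)\n",
              ns[1], ns[2], ns[3]))
  print(unclass(x)[, , , drop = FALSE])
  invisible(x)
}

#' Table of observed counts for a variable triple
#'
#' A thin carrier for empirical data: one row per observed cell
#' \code{(x, y, z)} with a nonnegative count. Symbols are 0-based integers.
#'
#' @param x,y,z integer vectors of 0-based symbols.
#' @param count nonnegative integer vector of counts.
#' @return A data frame of class \code{"count_table"} with columns
#'   \code{x, y, z, count}.
#' @export
count_table <- function(x, y, z, count) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  count <- as.numeric(count)
  n <- length(count)
  if (length(x) != n || length(y) != n || length(z) != n)
    .stopf("x, y, z and count must have equal length")
  if (any(is.na(c(x, y, z))) || any(c(x, y, z) < 0L))
    .stopf("symbols must be nonnegative integers")
  if (any(is.na(count)) || any(count < 0) || any(count != round(count)))
    .stopf("counts must be nonnegative integers")
  structure(data.frame(x = x, y = y, z = z, count = count),
            class = c("count_table", "data.frame"))
}

#' Normalise a count table into a joint distribution
#'
#' Aggregates duplicate rows, checks all symbols lie within the declared
#' alphabets, and divides by the total count. Unobserved cells get
#' probability zero.
#'
#' @param counts a [count_table()].
#' @param alphabet_sizes integer vector \code{c(Nx, Ny, Nz)}; defaults to the
#'   smallest alphabets containing the observed symbols.
#' @return A [joint_distribution()].
#' @examples
#' ct <- count_table(c(0, 1), c(0, 1), c(0, 1), c(1, 1))
#' normalize_counts(ct, c(2, 2, 2))
#' @export
normalize_counts <- function(counts, alphabet_sizes = NULL) {
  if (!inherits(counts, "count_table"))
    counts <- count_table(counts$x, counts$y, counts$z, counts$count)
  if (is.null(alphabet_sizes))
    alphabet_sizes <- c(max(counts$x), max(counts$y), max(counts$z)) + 1L
  alphabet_sizes <- as.integer(alphabet_sizes)
  tot <- sum(counts$count)
  if (tot <= 0) .stopf("total count is zero; nothing to normalise")
  if (any(counts$x >= alphabet_sizes[1]) || any(counts$y >= alphabet_sizes[2]) ||
      any(counts$z >= alphabet_sizes[3]))
    .stopf("symbol out of range for alphabet sizes (%s)",
           paste(alphabet_sizes, collapse = ", "))
  p <- array(0, alphabet_sizes)
  idx <- cbind(counts$x + 1L, counts$y + 1L, counts$z + 1L)
  for (i in seq_len(nrow(idx)))
    p[idx[i, 1], idx[i, 2], idx[i, 3]] <- p[idx[i, 1], idx[i, 2], idx[i, 3]] +
      counts$count[i]
  joint_distribution(p / tot, alphabet_sizes)
}

# Parse a variable-subset argument into sorted dimension indices 1 = X,
# 2 = Y, 3 = Z. Accepts c("X","Z"), "xz", c(1,3).
.parse_subset <- function(subset, allow_empty = FALSE) {
  if (is.numeric(subset)) {
    dims <- sort(unique(as.integer(subset)))
  } else {
    chars <- toupper(unlist(strsplit(as.character(subset), "", fixed = TRUE)))
    chars <- chars[chars %in% c("X", "Y", "Z")]
    dims <- sort(unique(match(chars, c("X", "Y", "Z"))))
  }
  if (length(dims) == 0L && !allow_empty)
    .stopf("variable subset must name at least one of X, Y, Z")
  if (any(is.na(dims)) || any(dims < 1L) || any(dims > 3L))
    .stopf("variable subset must be drawn from {X, Y, Z}")
  dims
}

# Marginalise a joint distribution onto the given dimensions and return the
# probability vector of the marginal.
.marginal_vec <- function(dist, dims) {
  if (length(dims) == 3L) return(as.vector(dist))
  as.vector(apply(unclass(dist), dims, sum))
}

#' Shannon entropy of a variable subset
#'
#' Marginalises the joint tensor onto \code{subset} and returns the entropy
#' \eqn{-\sum p \log_2 p} in bits, with the convention \eqn{0 \log 0 = 0}.
#'
#' @param dist a [joint_distribution()].
#' @param subset which variables, e.g. \code{"X"}, \code{c("X", "Z")},
#'   \code{"XYZ"}.
#' @return Entropy in bits.
#' @export
entropy <- function(dist, subset) {
  stopifnot(inherits(dist, "joint_distribution"))
  dims <- .parse_subset(subset)
  .ent(.marginal_vec(dist, dims))
}

#' Mutual information between variable subsets
#'
#' Computes \eqn{I(A : B | C)} in bits from joint entropies:
#' \eqn{I(A:B|C) = H(AC) + H(BC) - H(C) - H(ABC)}, with \eqn{H(\emptyset)=0}.
#'
#' @param dist a [joint_distribution()].
#' @param side_a,side_b nonempty, disjoint variable subsets.
#' @param given optional conditioning subset, disjoint from both sides.
#' @return Mutual information in bits.
#' @examples
#' p <- array(1 / 8, c(2, 2, 2)) # independent fair bits
#' mutual_information(joint_distribution(p), "X", "Y")
#' @export
mutual_information <- function(dist, side_a, side_b, given = character()) {
  stopifnot(inherits(dist, "joint_distribution"))
  a <- .parse_subset(side_a)
  b <- .parse_subset(side_b)
  g <- .parse_subset(given, allow_empty = TRUE)
  if (length(intersect(a, b)) || length(intersect(a, g)) ||
      length(intersect(b, g)))
    .stopf("side_a, side_b and given must be pairwise disjoint")
  h <- function(dims) if (length(dims)) .ent(.marginal_vec(dist, dims)) else 0
  h(sort(union(a, g))) + h(sort(union(b, g))) - h(g) -
    h(sort(Reduce(union, list(a, b, g))))
}

#' All classical Shannon measures of a variable triple
#'
#' Computes the seven joint entropies, the six mutual informations used
#' throughout the package, the interaction information II, the
#' co-information CI (\eqn{CI = -II} for three variables) and the
#' multi-information (total correlation)
#' \eqn{\Omega = H_X + H_Y + H_Z - H_{XYZ}}. All values in bits.
#'
#' @param dist a [joint_distribution()].
#' @return An object of class \code{"shannon_profile"}: a named list with
#'   entries \code{HX, HY, HZ, HXY, HXZ, HYZ, HXYZ}, \code{IZ_X, IZ_Y, IX_Y,
#'   IZ_XY, IY_XZ, IX_YZ}, \code{II}, \code{CI}, \code{omega}.
#' @export
shannon_profile <- function(dist) {
  stopifnot(inherits(dist, "joint_distribution"))
  v <- unclass(dist)
  ns <- dim(v)
  M1 <- matrix(v, ns[1], ns[2] * ns[3])   # rows x, cols (y, z)
  M3 <- matrix(v, ns[1] * ns[2], ns[3])   # rows (x, y), cols z
  m_xy <- rowSums(M3)
  HX <- .ent(rowSums(M1))
  HY <- .ent(colSums(matrix(m_xy, ns[1], ns[2])))
  HZ <- .ent(colSums(M3))
  HXY <- .ent(m_xy)
  HXZ <- .ent(rowSums(matrix(aperm(v, c(1, 3, 2)), ns[1] * ns[3], ns[2])))
  HYZ <- .ent(colSums(M1))
  HXYZ <- .ent(as.vector(v))
  CI <- HX + HY + HZ - HXY - HXZ - HYZ + HXYZ
  structure(list(
    HX = HX, HY = HY, HZ = HZ,
    HXY = HXY, HXZ = HXZ, HYZ = HYZ, HXYZ = HXYZ,
    IZ_X = HX + HZ - HXZ,
    IZ_Y = HY + HZ - HYZ,
    IX_Y = HX + HY - HXY,
    IZ_XY = HXY + HZ - HXYZ,
    IY_XZ = HXZ + HY - HXYZ,
    IX_YZ = HYZ + HX - HXYZ,
    II = -CI,
    CI = CI,
    omega = HX + HY + HZ - HXYZ
  ), class = "shannon_profile")
}

#' @export
print.shannon_profile <- function(x, digits = 4, ...) {
  cat("<shannon_profile> (bits)\n")
  cat(sprintf("  H:  X=%.*f Y=%.*f Z=%.*f XY=%.*f XZ=%.*f YZ=%.*f XYZ=%.*f\n",
              digits, x$HX, digits, x$HY, digits, x$HZ, digits, x$HXY,
              digits, x$HXZ, digits, x$HYZ, digits, x$HXYZ))
  cat(sprintf("  I:  Z:X=%.*f Z:Y=%.*f X:Y=%.*f Z:XY=%.*f\n",
              digits, x$IZ_X, digits, x$IZ_Y, digits, x$IX_Y, digits, x$IZ_XY))
  cat(sprintf("  II=%.*f  CI=%.*f  omega=%.*f\n",
              digits, x$II, digits, x$CI, digits, x$omega))
  invisible(x)
}
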