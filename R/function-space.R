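#' Discrete function of two source variables
#'
#' A total function \eqn{Z = f(X, Y)} on a common alphabet
#' \eqn{\{0, \dots, N-1\}}, stored as an N-by-N table with rows indexed by x
#' and columns by y.
#'
#' @param table integer matrix of output symbols in \code{[0, N)}; N is taken
#'   from the matrix dimension.
#' @return An object of class \code{"discrete_function"}.
#' @examples
#' and2 <- discrete_function(matrix(c(0, 0, 0, 1), 2, 2)) # binary AND
#' @export
discrete_function <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  if (ncol(table) != n) .stopf("function table must be square")
  storage.mode(table) <- "integer"
  if (any(is.na(table)) || any(table < 0L) || any(table >= n))
    .stopf("table entries must be symbols in [0, %d)", n)
  structure(table, class = "discrete_function", N = n)
}

#' @export
print.discrete_function <- function(x, ...) {
  cat(sprintf("<discrete_function> N = %d, table (rows = x, cols = y):\n",
              attr(x, "N")))
  print(unclass(x))
  invisible(x)
}

# Digit matrix of all N^(N^2) functions: one row per function, one column
# per table cell in column-major (x fastest) order; big-endian base-N
# counting so function 0 is the constant 0 and row order is lexicographic.
.function_digits <- function(N) {
  ncells <- N * N
  nfun <- N^ncells
  if (nfun > 2^26) .stopf("enumeration of %g functions is not supported", nfun)
  id <- seq_len(nfun) - 1
  digits <- matrix(0L, nfun, ncells)
  for (j in seq_len(ncells))
    digits[, j] <- as.integer((id %/% N^(ncells - j)) %% N)
  digits
}

#' Enumerate all discrete functions Z = f(X, Y)
#'
#' Generates every total function on the N-letter alphabet, exactly once, in
#' deterministic base-N counting order over the flattened table (the first
#' function is the constant 0). There are \eqn{N^{N^2}} such functions:
#' 16 for N = 2 and 19,683 for N = 3.
#'
#' @param N alphabet size, at least 2. Exhaustive enumeration beyond N = 3
#'   (4 billion-plus functions for N = 4 would be impractical; N = 4 alone is
#'   ~4.3e9) requires \code{exhaustive_override = TRUE} and is guarded.
#' @param exhaustive_override set \code{TRUE} to permit N = 4.
#' @return A list of [discrete_function()] objects.
#' @export
enumerate_functions <- function(N, exhaustive_override = FALSE) {
  N <- as.integer(N)
  if (N < 2L) .stopf("N must be at least 2")
  if (N > 3L && !exhaustive_override)
    .stopf("exhaustive enumeration for N > 3 requires exhaustive_override = TRUE")
  digits <- .function_digits(N)
  lapply(seq_len(nrow(digits)), function(i)
    discrete_function(matrix(digits[i, ], N, N)))
}

#' Joint distribution induced by a discrete function
#'
#' With input distribution \eqn{p(x, y)} over the sources,
#' \eqn{p(x, y, z) = p(x, y)} if \eqn{z = f(x, y)} and 0 otherwise.
#'
#' @param f a [discrete_function()].
#' @param input_dist N-by-N nonnegative matrix summing to 1; defaults to the
#'   uniform i.i.d. input (every cell \eqn{1/N^2}).
#' @return A [joint_distribution()].
#' @export
function_to_distribution <- function(f, input_dist = NULL) {
  stopifnot(inherits(f, "discrete_function"))
  N <- attr(f, "N")
  if (is.null(input_dist)) input_dist <- matrix(1 / N^2, N, N)
  input_dist <- as.matrix(input_dist)
  if (!identical(dim(input_dist), c(N, N)) || any(input_dist < -1e-15) ||
      abs(sum(input_dist) - 1) > 1e-12)
    .stopf("input_dist must be an N x N probability matrix")
  p <- array(0, c(N, N, N))
  for (x in seq_len(N))
    for (y in seq_len(N))
      p[x, y, unclass(f)[x, y] + 1L] <- input_dist[x, y]
  joint_distribution(p, c(N, N, N))
}

# Vectorised delta computation for every function in a digit matrix under a
# common input distribution. Returns a data frame with one row per function.
.atlas_deltas <- function(digits, w_mat) {
  N <- nrow(w_mat)
  nfun <- nrow(digits)
  w <- as.vector(w_mat)                       # cell order: x fastest
  xlx <- function(m) { m2 <- m; pos <- m2 > .zero_tol
                       m2[pos] <- m2[pos] * log2(m2[pos]); m2[!pos] <- 0; m2 }
  HX <- .ent(rowSums(w_mat)); HY <- .ent(colSums(w_mat))
  HXY <- .ent(w); HXYZ <- HXY                 # one z per (x, y) cell
  x_of_cell <- rep(seq_len(N), times = N)
  y_of_cell <- rep(seq_len(N), each = N)
  HZ <- numeric(nfun); HXZ <- numeric(nfun); HYZ <- numeric(nfun)
  for (k in 0:(N - 1)) {
    A <- (digits == k) * rep(w, each = nfun)  # nfun x ncells
    HZ <- HZ - as.vector(xlx(rowSums(A)))
    for (v in seq_len(N)) {
      HXZ <- HXZ - as.vector(xlx(rowSums(A[, x_of_cell == v, drop = FALSE])))
      HYZ <- HYZ - as.vector(xlx(rowSums(A[, y_of_cell == v, drop = FALSE])))
    }
  }
  omega <- HX + HY + HZ - HXYZ
  data.frame(
    fun_id = seq_len(nfun) - 1L,
    deltaX = (-HX + HXY + HXZ - HXYZ) / omega,
    deltaY = (-HY + HXY + HYZ - HXYZ) / omega,
    deltaZ = (-HZ + HXZ + HYZ - HXYZ) / omega,
    omega = omega)
}

#' Atlas of all discrete functions in delta space
#'
#' Enumerates every function \eqn{Z = f(X, Y)} on the N-letter alphabet,
#' computes its delta coordinates under a common input distribution, and
#' groups functions sharing a delta point into families. For N = 3 with
#' uniform i.i.d. inputs the 19,683 functions fall into 105 families.
#' Functions whose output is independent of the inputs (the constants) have
#' \eqn{\Omega = 0}, carry no delta point, and are collected in a separate
#' degenerate bucket rather than a family.
#'
#' @param N alphabet size (2 or 3; see [enumerate_functions()]).
#' @param input_dist source distribution, default uniform i.i.d.
#' @param grouping_digits delta values are rounded to this many decimals
#'   before grouping (default 9; exact N = 2/3 delta points are separated by
#'   far more than 1e-9).
#' @param exhaustive_override passed to the enumeration guard.
#' @return An object of class \code{"function_atlas"}: a list with
#'   \code{entries} (data frame: fun_id, table digits, deltas, omega,
#'   family_id; NA family for degenerate functions), \code{families} (data
#'   frame: family_id, delta point, member count, representative fun_id),
#'   \code{degenerate} (fun_ids with \eqn{\Omega = 0}) and \code{N}.
#' @export
build_atlas <- function(N, input_dist = NULL, grouping_digits = 9,
                        exhaustive_override = FALSE) {
  N <- as.integer(N)
  if (N < 2L) .stopf("N must be at least 2")
  if (N > 3L && !exhaustive_override)
    .stopf("exhaustive atlas for N > 3 requires exhaustive_override = TRUE")
  if (is.null(input_dist)) input_dist <- matrix(1 / N^2, N, N)
  input_dist <- as.matrix(input_dist)
  digits <- .function_digits(N)
  ent <- .atlas_deltas(digits, input_dist)
  degenerate <- ent$omega < 1e-12
  ent$deltaX[degenerate] <- NA_real_
  ent$deltaY[degenerate] <- NA_real_
  ent$deltaZ[degenerate] <- NA_real_
  key <- ifelse(degenerate, NA_character_,
                paste(round(ent$deltaX, grouping_digits),
                      round(ent$deltaY, grouping_digits),
                      round(ent$deltaZ, grouping_digits), sep = "/"))
  fam_keys <- unique(key[!degenerate])
  # stable family ids in order of first appearance (= lexicographically
  # smallest member, since enumeration order is lexicographic)
  ent$family_id <- match(key, fam_keys)
  rep_idx <- match(fam_keys, key)
  families <- data.frame(
    family_id = seq_along(fam_keys),
    deltaX = ent$deltaX[rep_idx],
    deltaY = ent$deltaY[rep_idx],
    deltaZ = ent$deltaZ[rep_idx],
    omega = ent$omega[rep_idx],
    n_members = as.integer(table(factor(ent$family_id,
                                        levels = seq_along(fam_keys)))),
    representative = ent$fun_id[rep_idx])
  ent$table <- apply(digits, 1, paste, collapse = "")
  structure(list(entries = ent[, c("fun_id", "table", "deltaX", "deltaY",
                                   "deltaZ", "omega", "family_id")],
                 families = families,
                 degenerate = ent$fun_id[degenerate],
                 N = N, input_dist = input_dist),
            class = "function_atlas")
}

#' @export
print.function_atlas <- function(x, ...) {
  cat(sprintf(paste0("<function_atlas> N = %d: %d functions, %d families, ",
                     "%d degenerate (omega = 0)\n"),
              x$N, nrow(x$entries), nrow(x$families), length(x$degenerate)))
  invisible(x)
}

#' Retrieve the representative function of an atlas family
#'
#' @param atlas a [build_atlas()] result.
#' @param family_id family identifier.
#' @return The lexicographically smallest member as a [discrete_function()].
#' @export
family_representative <- function(atlas, family_id) {
  stopifnot(inherits(atlas, "function_atlas"))
  row <- atlas$families[atlas$families$family_id == family_id, ]
  if (nrow(row) != 1L) .stopf("unknown family id %s", family_id)
  digits <- as.integer(strsplit(
    atlas$entries$table[atlas$entries$fun_id == row$representative],
    "")[[1]])
  discrete_function(matrix(digits, atlas$N, atlas$N))
}

#' Export an atlas as a TSV table
#'
#' One row per function: id, table digits, delta coordinates, omega and
#' family id (empty for degenerate functions).
#'
#' @param atlas a [build_atlas()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_atlas_tsv <- function(atlas, path) {
  stopifnot(inherits(atlas, "function_atlas"))
  utils::write.table(atlas$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
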