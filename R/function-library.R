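# Library-and-query workflow: precompute, for every function family, the
# delta point, Q plane, a sampled Q delta-cloud and the PID by both
# solvers; then match empirical delta coordinates to the nearest family.
# Because a family's Q cloud covers distributions with dependent sources,
# the match tolerates source coupling (e.g. linkage disequilibrium) that
# moves empirical points off the i.i.d. function plane.

#' Build a function library for delta-coordinate matching
#'
#' Enumerates the function atlas for alphabet size N, and for the
#' representative function of every non-degenerate family records: the base
#' delta point, the Q-plane coefficients, a seeded sample of the Q set's
#' delta-cloud, and the PID components by both the optimisation
#' (\code{"broja"}) and pointwise (\code{"ppid"}) solvers.
#'
#' @param N alphabet size (2 or 3).
#' @param input_dist source distribution for the atlas (default uniform
#'   i.i.d.).
#' @param samples_per_family Q-cloud sample size per family (>= 1; sample 1
#'   is always the family's base point).
#' @param seed integer seed controlling all sampling; builds are
#'   deterministic for a fixed seed.
#' @param broja_starts multistart count for the optimisation solver.
#' @return An object of class \code{"function_library"}: list with
#'   \code{metadata} (N, seed, samples_per_family, version),
#'   \code{atlas}, and \code{entries} -- one record per family holding the
#'   representative [discrete_function()], delta point, [q_plane()]
#'   coefficients, the cloud (matrix of delta coordinates) and both
#'   \code{"pid"} objects.
#' @export
build_function_library <- function(N, input_dist = NULL,
                                   samples_per_family = 200L, seed = 1L,
                                   broja_starts = 3L) {
  samples_per_family <- as.integer(samples_per_family)
  if (samples_per_family < 1L) .stopf("samples_per_family must be >= 1")
  atlas <- build_atlas(N, input_dist = input_dist)
  fams <- atlas$families
  entries <- vector("list", nrow(fams))
  for (i in seq_len(nrow(fams))) {
    f <- family_representative(atlas, fams$family_id[i])
    dist <- function_to_distribution(f, atlas$input_dist)
    delta <- info_deltas(dist)
    plane <- q_plane(dist)
    param <- q_parameterization(dist)
    qs <- sample_q(param, samples_per_family,
                   seed = .child_seed(seed, 1000L + i))
    cloud <- as.matrix(qs$deltas[, c("deltaX", "deltaY", "deltaZ")])
    cloud[1, ] <- c(delta$deltaX, delta$deltaY, delta$deltaZ)
    entries[[i]] <- list(
      family_id = fams$family_id[i],
      representative = f,
      delta = c(deltaX = delta$deltaX, deltaY = delta$deltaY,
                deltaZ = delta$deltaZ),
      omega = delta$omega,
      plane = plane,
      cloud = cloud,
      pid_broja = pid_broja(dist, n_starts = broja_starts,
                            seed = .child_seed(seed, 2000L + i)),
      pid_ppid = pid_ppid(dist))
  }
  structure(list(metadata = list(N = as.integer(N), seed = as.integer(seed),
                                 samples_per_family = samples_per_family,
                                 version = "1"),
                 atlas = atlas, entries = entries),
            class = "function_library")
}

#' @export
print.function_library <- function(x, ...) {
  cat(sprintf(
    "<function_library> N = %d: %d families, %d cloud points each (seed %d)\n",
    x$metadata$N, length(x$entries), x$metadata$samples_per_family,
    x$metadata$seed))
  invisible(x)
}

#' Match observed data to the nearest function families
#'
#' Two query routes are supported. Given only delta coordinates, families
#' are ranked by the Euclidean distance from the observed delta point to
#' the nearest point of each family's sampled Q cloud. Given the full
#' empirical distribution (\code{empirical}), families are ranked by the
#' distance from the data to the set \eqn{Q_i} itself: since \eqn{Q_i}
#' contains exactly the distributions with family i's (X, Z) and (Y, Z)
#' marginals, that distance is the root-mean-square deviation of the
#' empirical source-target marginals from the family's. The marginal route
#' is markedly more robust to output noise (which pushes delta coordinates
#' off every Q cloud) and is used by the analysis pipeline whenever the
#' empirical tensor is available. Ties are broken by the point-to-plane
#' distance to the family's Q plane, then by family id. Querying a library
#' member's own delta point returns that family at distance 0.
#'
#' @param library a [build_function_library()] result.
#' @param observed a \code{"delta_coords"} object or numeric
#'   \code{c(deltaX, deltaY, deltaZ)}.
#' @param k number of families to return (default 5).
#' @param empirical optional [joint_distribution()] of the observed data;
#'   switches to the marginal-deviation distance.
#' @return An object of class \code{"query_result"}: data frame with one
#'   row per returned family (rank, family_id, distance, plane_distance,
#'   the family's PID components by both solvers) plus attributes
#'   \code{query} and \code{representatives} (list of
#'   [discrete_function()]).
#' @export
query_function_library <- function(library, observed, k = 5L,
                                   empirical = NULL) {
  stopifnot(inherits(library, "function_library"))
  if (length(library$entries) == 0L) .stopf("the library is empty")
  if (inherits(observed, "delta_coords"))
    observed <- c(observed$deltaX, observed$deltaY, observed$deltaZ)
  observed <- as.numeric(observed)
  if (length(observed) != 3L || any(!is.finite(observed)))
    .stopf("observed delta coordinates must be three finite numbers")
  input_dist <- if (!is.null(library$atlas)) library$atlas$input_dist
  plane_dist_of <- function(e) {
    pl <- e$plane
    gn <- sqrt(2 * pl$coef_dxy^2 + pl$coef_dz^2)
    if (gn < 1e-12) Inf else
      abs(pl$coef_dxy * (observed[1] - observed[2]) +
            pl$coef_dz * (1 - observed[3])) / gn
  }
  if (is.null(empirical)) {
    dist <- vapply(library$entries, function(e) {
      cl <- e$cloud[stats::complete.cases(e$cloud), , drop = FALSE]
      sqrt(min((cl[, 1] - observed[1])^2 + (cl[, 2] - observed[2])^2 +
                 (cl[, 3] - observed[3])^2))
    }, 1)
  } else {
    stopifnot(inherits(empirical, "joint_distribution"))
    exz <- apply(unclass(empirical), c(1, 3), sum)
    eyz <- apply(unclass(empirical), c(2, 3), sum)
    dist <- vapply(library$entries, function(e) {
      d <- function_to_distribution(e$representative, input_dist)
      sqrt(sum((apply(unclass(d), c(1, 3), sum) - exz)^2) +
             sum((apply(unclass(d), c(2, 3), sum) - eyz)^2))
    }, 1)
  }
  pdist <- vapply(library$entries, plane_dist_of, 1)
  fid <- vapply(library$entries, `[[`, 1L, "family_id")
  ord <- order(dist, pdist, fid)
  k <- min(as.integer(k), length(ord))
  sel <- ord[seq_len(k)]
  out <- data.frame(
    rank = seq_len(k),
    family_id = fid[sel],
    distance = dist[sel],
    plane_distance = pdist[sel],
    broja_UX = vapply(library$entries[sel], function(e) e$pid_broja$UX, 1),
    broja_UY = vapply(library$entries[sel], function(e) e$pid_broja$UY, 1),
    broja_R = vapply(library$entries[sel], function(e) e$pid_broja$R, 1),
    broja_S = vapply(library$entries[sel], function(e) e$pid_broja$S, 1),
    ppid_UX = vapply(library$entries[sel], function(e) e$pid_ppid$UX, 1),
    ppid_UY = vapply(library$entries[sel], function(e) e$pid_ppid$UY, 1),
    ppid_R = vapply(library$entries[sel], function(e) e$pid_ppid$R, 1),
    ppid_S = vapply(library$entries[sel], function(e) e$pid_ppid$S, 1))
  class(out) <- c("query_result", "data.frame")
  attr(out, "query") <- observed
  attr(out, "representatives") <-
    lapply(library$entries[sel], `[[`, "representative")
  out
}

#' Serialise a function library to a JSON archive plus a TSV cloud table
#'
#' The JSON file holds the metadata and per-family records (representative
#' table, delta point, plane coefficients, both PIDs); the TSV file holds
#' the sampled delta clouds (family_id, sample, deltaX, deltaY, deltaZ).
#'
#' @param library a [build_function_library()] result.
#' @param json_path,tsv_path output paths.
#' @return \code{json_path}, invisibly.
#' @export
write_function_library <- function(library, json_path, tsv_path) {
  stopifnot(inherits(library, "function_library"))
  ent <- lapply(library$entries, function(e) {
    list(family_id = e$family_id,
         table = paste(as.vector(unclass(e$representative)), collapse = ""),
         delta = unname(e$delta),
         omega = e$omega,
         plane = list(c1 = e$plane$c1, c2 = e$plane$c2, c3 = e$plane$c3,
                      c4 = e$plane$c4),
         pid_broja = list(UX = e$pid_broja$UX, UY = e$pid_broja$UY,
                          R = e$pid_broja$R, S = e$pid_broja$S),
         pid_ppid = list(UX = e$pid_ppid$UX, UY = e$pid_ppid$UY,
                         R = e$pid_ppid$R, S = e$pid_ppid$S))
  })
  jsonlite::write_json(list(metadata = library$metadata, entries = ent),
                       json_path, auto_unbox = TRUE, digits = NA)
  clouds <- do.call(rbind, lapply(library$entries, function(e) {
    data.frame(family_id = e$family_id,
               sample = seq_len(nrow(e$cloud)),
               deltaX = e$cloud[, 1], deltaY = e$cloud[, 2],
               deltaZ = e$cloud[, 3])
  }))
  utils::write.table(clouds, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(json_path)
}

#' Read a function library archive written by [write_function_library()]
#'
#' Restores a queryable library (metadata, per-family records, clouds).
#' The atlas itself is not stored in the archive and is not restored.
#'
#' @param json_path,tsv_path archive paths.
#' @return A \code{"function_library"} object (with \code{atlas = NULL}).
#' @export
read_function_library <- function(json_path, tsv_path) {
  raw <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  clouds <- utils::read.delim(tsv_path)
  N <- as.integer(raw$metadata$N)
  entries <- lapply(raw$entries, function(e) {
    digits <- as.integer(strsplit(e$table, "")[[1]])
    cl <- clouds[clouds$family_id == e$family_id, ]
    plane <- structure(list(c1 = e$plane$c1, c2 = e$plane$c2,
                            c3 = e$plane$c3, c4 = e$plane$c4,
                            coef_dxy = e$plane$c1 - e$plane$c4,
                            coef_dz = e$plane$c3 - e$plane$c2,
                            degenerate =
                              abs(e$plane$c1 - e$plane$c4) < 1e-12 &&
                              abs(e$plane$c3 - e$plane$c2) < 1e-12),
                       class = "q_plane")
    list(family_id = as.integer(e$family_id),
         representative = discrete_function(matrix(digits, N, N)),
         delta = c(deltaX = e$delta[1], deltaY = e$delta[2],
                   deltaZ = e$delta[3]),
         omega = e$omega,
         plane = plane,
         cloud = as.matrix(cl[, c("deltaX", "deltaY", "deltaZ")]),
         pid_broja = structure(c(e$pid_broja, solver = "broja"),
                               class = "pid"),
         pid_ppid = structure(c(e$pid_ppid, solver = "ppid"),
                              class = "pid"))
  })
  structure(list(metadata = raw$metadata, atlas = NULL, entries = entries),
            class = "function_library")
}
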