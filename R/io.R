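# File formats and the command-line front end. Count tables travel as TSV
# ("x<TAB>y<TAB>z<TAB>count", 0-based integer symbols) or as JSON (dense
# nested array with declared alphabet sizes); analysis reports are JSON.

#' Read a count table or dense tensor from disk
#'
#' TSV dialect: a header line \code{x<TAB>y<TAB>z<TAB>count} followed by
#' one row per cell, 0-based integer symbols, UTF-8, LF or CRLF line
#' endings; duplicated (x, y, z) rows are summed. JSON dialect: an object
#' with \code{alphabet_sizes} and a dense nested array \code{p} (or
#' \code{counts}) indexed \code{[x][y][z]}.
#'
#' @param path input file.
#' @param format \code{"tsv"}, \code{"json"} or \code{"auto"} (by file
#'   extension, default).
#' @param one_based set \code{TRUE} if the TSV symbols are 1-based (e.g.
#'   genetics encodings); they are shifted down on read.
#' @return A [count_table()] (counts may be non-integer when the JSON
#'   carries probabilities; they are rescaled to sum to 1e6 in that case).
#' @examples
#' path <- system.file("extdata", "rdnerr.tsv", package = "infodelta")
#' normalize_counts(read_counts(path))
#' @export
read_counts <- function(path, format = c("auto", "tsv", "json"),
                        one_based = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    arr <- raw$p
    if (is.null(arr)) arr <- raw$counts
    if (is.null(arr)) .stopf("JSON input must contain a 'p' or 'counts' array")
    ns <- as.integer(raw$alphabet_sizes)
    if (length(ns) != 3L) .stopf("JSON input must declare 3 alphabet_sizes")
    vals <- array(as.numeric(arr), rev(ns))  # nested [x][y][z] parses z-fastest
    vals <- aperm(vals, c(3, 2, 1))
    if (abs(sum(vals) - 1) < 1e-6) vals <- vals * 1e6
    idx <- which(vals != 0, arr.ind = TRUE)
    return(count_table(idx[, 1] - 1L, idx[, 2] - 1L, idx[, 3] - 1L,
                       round(vals[idx])))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 1L) .stopf("empty count file: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(tolower(trimws(header)), c("x", "y", "z", "count")))
    .stopf("malformed header %s; expected 'x<TAB>y<TAB>z<TAB>count'",
           deparse(lines[1]))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) .stopf("no data rows in %s", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) .stopf("rows must have 4 tab-separated fields")
  m <- matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE)
  if (any(is.na(m))) .stopf("non-numeric field in count table")
  if (any(m[, 1:3] != round(m[, 1:3]))) .stopf("symbols must be integers")
  if (any(m[, 4] < 0)) .stopf("counts must be nonnegative")
  off <- if (one_based) 1L else 0L
  if (any(m[, 1:3] - off < 0)) .stopf("negative symbol after offset correction")
  agg <- stats::aggregate(list(count = m[, 4]),
                          by = list(x = m[, 1] - off, y = m[, 2] - off,
                                    z = m[, 3] - off), FUN = sum)
  count_table(agg$x, agg$y, agg$z, agg$count)
}

#' Write a count table in the package TSV dialect
#'
#' @param counts a [count_table()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  utils::write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Full analysis report for an empirical count table
#'
#' Normalises the counts, computes the Shannon profile, the delta
#' coordinates (explicitly marked undefined when \eqn{\Omega = 0}), the PID
#' by the requested solver(s) with their consistency residuals, and, if a
#' library is supplied, the nearest-family query.
#'
#' @param counts a [count_table()].
#' @param alphabet_sizes optional alphabet sizes (default: inferred).
#' @param solver \code{"broja"}, \code{"ppid"} or \code{"both"}.
#' @param library optional [build_function_library()] result for matching.
#' @param k families to report from the query.
#' @param seed seed for the optimisation solver.
#' @return A list of class \code{"analysis_report"} (serialisable to JSON
#'   with [jsonlite::write_json()]).
#' @export
analyze_counts <- function(counts, alphabet_sizes = NULL,
                           solver = c("both", "broja", "ppid"),
                           library = NULL, k = 5L, seed = 1L) {
  solver <- match.arg(solver)
  dist <- normalize_counts(counts, alphabet_sizes)
  sp <- shannon_profile(dist)
  report <- list(
    input = list(n_records = nrow(counts), total_count = sum(counts$count),
                 alphabet_sizes = attr(dist, "alphabet_sizes"),
                 digest = .counts_digest(counts)),
    shannon = unclass(sp))
  if (sp$omega < 1e-12) {
    report$deltas <- list(defined = FALSE,
                          reason = "omega = 0: variables are independent")
  } else {
    d <- info_deltas(dist)
    report$deltas <- list(defined = TRUE, deltaX = d$deltaX,
                          deltaY = d$deltaY, deltaZ = d$deltaZ,
                          omega = d$omega,
                          plane_distance = plane_distance(d))
  }
  pids <- list()
  if (solver %in% c("broja", "both")) pids$broja <- pid_broja(dist, seed = seed)
  if (solver %in% c("ppid", "both")) pids$ppid <- pid_ppid(dist)
  report$pid <- lapply(pids, function(p) {
    out <- list(UX = p$UX, UY = p$UY, R = p$R, S = p$S)
    if (isTRUE(report$deltas$defined)) {
      cons <- check_consistency(p, dist)
      out$consistency <- stats::setNames(cons$residual, cons$identity)
    }
    out
  })
  if (!is.null(library) && isTRUE(report$deltas$defined)) {
    qr <- query_function_library(
      library, c(report$deltas$deltaX, report$deltas$deltaY,
                 report$deltas$deltaZ), k = k, empirical = dist)
    report$query <- as.data.frame(qr)
  }
  class(report) <- "analysis_report"
  report
}

# stable content digest of a count table (order-independent)
.counts_digest <- function(counts) {
  o <- order(counts$x, counts$y, counts$z)
  txt <- paste(counts$x[o], counts$y[o], counts$z[o], counts$count[o],
               sep = ",", collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

.cli_usage <- paste(
  "usage: infodelta <command> [options]",
  "commands:",
  "  measures --in FILE [--out FILE]           Shannon profile",
  "  deltas   --in FILE [--out FILE]           delta coordinates",
  "  pid      --in FILE --solver S [--out FILE]  PID (broja|ppid|both)",
  "  atlas    --n N [--out FILE] [--tsv FILE]  function atlas",
  "  qset     --in FILE --samples K --seed S [--tsv FILE]  sample Q",
  "  library  build --n N --samples K --seed S --json F --tsv F",
  "  library  query --json F --tsv F --delta dX,dY,dZ [--k K] [--out FILE]",
  "  synth    --table DIGITS --n N --seed S [--noise E] [--coupling R]",
  "           [--out FILE]                     synthetic count table",
  sep = "\n")

.parse_argv <- function(argv) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(argv) || startsWith(argv[i + 1L], "--"))
        .stopf("option --%s requires a value", key)
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

.report_out <- function(x, out) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows", na = "null")
  if (is.null(out)) cat(json, "\n") else writeLines(json, out)
}

#' Command-line entry point
#'
#' A thin argv-driven front end over the package functions; see
#' \code{system.file("cli", "infodelta", package = "infodelta")} for the
#' executable Rscript wrapper. Subcommands: \code{measures}, \code{deltas},
#' \code{pid}, \code{atlas}, \code{qset}, \code{library build},
#' \code{library query}, \code{synth}. Reports are JSON on stdout or
#' \code{--out}; log lines go to stderr. All randomised commands take
#' \code{--seed}.
#'
#' @param argv character vector of arguments (as from
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return Integer exit status, invisibly (0 on success).
#' @export
run_command <- function(argv) {
  status <- tryCatch({
    if (length(argv) < 1L) { message(.cli_usage); return(invisible(2L)) }
    cmd <- argv[1]
    sub <- character()
    rest <- argv[-1]
    if (cmd == "library") {
      if (length(rest) < 1L) .stopf("library needs a subcommand (build|query)")
      sub <- rest[1]; rest <- rest[-1]
    }
    o <- .parse_argv(rest)
    need <- function(name) {
      v <- o[[name]]
      if (is.null(v)) .stopf("missing required option --%s", name)
      v
    }
    switch(cmd,
      measures = {
        ct <- read_counts(need("in"))
        dist <- normalize_counts(ct)
        .msg("info", "measures: %d records, total count %g", nrow(ct),
             sum(ct$count))
        .report_out(unclass(shannon_profile(dist)), o[["out"]])
      },
      deltas = {
        ct <- read_counts(need("in"))
        dist <- normalize_counts(ct)
        sp <- shannon_profile(dist)
        if (sp$omega < 1e-12) {
          .msg("warn", "omega = 0: delta coordinates undefined")
          .report_out(list(defined = FALSE, omega = sp$omega,
                           reason = "variables are independent"), o[["out"]])
        } else {
          d <- info_deltas(dist)
          .report_out(list(defined = TRUE, deltaX = d$deltaX,
                           deltaY = d$deltaY, deltaZ = d$deltaZ,
                           omega = d$omega,
                           plane_distance = plane_distance(d)), o[["out"]])
        }
      },
      pid = {
        ct <- read_counts(need("in"))
        solver <- if (is.null(o[["solver"]])) "both" else o[["solver"]]
        seed <- as.integer(if (is.null(o[["seed"]])) 1L else o[["seed"]])
        rep <- analyze_counts(ct, solver = solver, seed = seed)
        .report_out(unclass(rep), o[["out"]])
      },
      atlas = {
        atlas <- build_atlas(as.integer(need("n")))
        .msg("info", "atlas: %d functions, %d families, %d degenerate",
             nrow(atlas$entries), nrow(atlas$families),
             length(atlas$degenerate))
        if (!is.null(o[["tsv"]])) write_atlas_tsv(atlas, o[["tsv"]])
        .report_out(list(N = atlas$N, n_functions = nrow(atlas$entries),
                         n_families = nrow(atlas$families),
                         n_degenerate = length(atlas$degenerate),
                         families = atlas$families), o[["out"]])
      },
      qset = {
        ct <- read_counts(need("in"))
        dist <- normalize_counts(ct)
        qs <- sample_q(q_parameterization(dist),
                       as.integer(need("samples")),
                       seed = as.integer(need("seed")))
        if (!is.null(o[["tsv"]])) write_q_sample_tsv(qs, o[["tsv"]])
        .report_out(list(n_samples = nrow(qs$theta),
                         n_params = ncol(qs$theta),
                         deltas = qs$deltas), o[["out"]])
      },
      library = {
        if (sub == "build") {
          lib <- build_function_library(
            as.integer(need("n")),
            samples_per_family = as.integer(need("samples")),
            seed = as.integer(need("seed")))
          write_function_library(lib, need("json"), need("tsv"))
          .msg("info", "library: %d families written", length(lib$entries))
        } else if (sub == "query") {
          lib <- read_function_library(need("json"), need("tsv"))
          delta <- as.numeric(strsplit(need("delta"), ",")[[1]])
          k <- as.integer(if (is.null(o[["k"]])) 5L else o[["k"]])
          qr <- query_function_library(lib, delta, k = k)
          .report_out(as.data.frame(qr), o[["out"]])
        } else .stopf("unknown library subcommand '%s'", sub)
      },
      synth = {
        digits <- as.integer(strsplit(need("table"), "")[[1]])
        N <- as.integer(round(sqrt(length(digits))))
        f <- discrete_function(matrix(digits, N, N))
        cfg <- generator_config(
          f, as.integer(need("n")),
          noise = as.numeric(if (is.null(o[["noise"]])) 0 else o[["noise"]]),
          coupling = as.numeric(
            if (is.null(o[["coupling"]])) 0 else o[["coupling"]]),
          seed = as.integer(need("seed")))
        ct <- generate_observations(cfg)
        if (is.null(o[["out"]])) {
          utils::write.table(as.data.frame(ct), sep = "\t", quote = FALSE,
                             row.names = FALSE)
        } else write_counts(ct, o[["out"]])
      },
      {
        message(sprintf("unknown command '%s'\n%s", cmd, .cli_usage))
        return(invisible(2L))
      })
    0L
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    1L
  })
  invisible(status)
}
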