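# Internal helpers shared across the package.

# Probabilities below this are treated as exact zeros in entropy sums
# (0 * log 0 == 0 by convention).
.zero_tol <- 1e-15

# Shannon entropy in bits of a probability vector (need not be normalised
# exactly; zeros are dropped).
.ent <- function(p) {
  p <- p[p > .zero_tol]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed, kept within the
# 32-bit integer range.
.child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msg <- function(level, fmt, ...) {
  if (level == "debug" && !isTRUE(getOption("infodelta.verbose")))
    return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
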