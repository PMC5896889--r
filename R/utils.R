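# Internal helpers shared across modules.

# Scoped seeding: set.seed(seed) for the duration of the calling function,
# restoring the caller's RNG state on exit.  Usage:
#   restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
# seed = NULL is a no-op (the ambient RNG stream is used), which lets
# high-level simulators seed once and call unseeded internals.
seed_scope <- function(seed) {
  if (is.null(seed)) return(function() invisible(NULL))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  function() {
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
    invisible(NULL)
  }
}

# Deterministic child seed (kept within 32-bit integer range).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Replicate a named vector into an n-row matrix (rows identical).
rep_rows <- function(v, n) {
  matrix(rep(v, each = n), nrow = n, dimnames = list(NULL, names(v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
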