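#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring global state afterwards.
# All stochastic gemkit functions take an explicit integer seed and route
# through this so no call mutates the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_ids <- function(ids, universe, what) {
  bad <- setdiff(ids, universe)
  if (length(bad)) {
    stop(sprintf("unknown %s: %s", what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
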