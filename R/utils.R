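#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' then restores the caller's RNG state, so package functions that take an
#' explicit seed never disturb user-level randomness.
#'
#' @param seed single integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Abort with a class so callers (and the CLI) can tell user errors apart
# from internal ones.
clrda_error <- function(msg, class = "clrda_error") {
  stop(structure(
    class = c(class, "clrda_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Integer-valued check that tolerates doubles such as 3 or 3.0.
is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Spawn a stream of child seeds from one master seed, each well below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}
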