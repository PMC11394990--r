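#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("config: 'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# stage-tagged stop(); every user-facing failure names the pipeline stage
stop_stage <- function(stage, ...) {
  stop(sprintf("%s: %s", stage, paste0(...)), call. = FALSE)
}

assert_scalar_number <- function(x, name, stage = "config") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_stage(stage, sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}
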