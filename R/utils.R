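`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state so that seeded package functions do
#' not disturb the caller's random stream. A `NULL` seed evaluates `code`
#' against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# stop() with a class so callers can distinguish configuration errors
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("spousim_config_error", "error")))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
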