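`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores whatever stream (if any) was active before.  All stochastic
#' package operations funnel through this so that a single integer seed
#' makes a run reproducible without disturbing the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

geomean <- function(x) exp(mean(log(x)))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
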