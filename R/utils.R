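`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set to `seed`, then
#' restores whatever stream was active before the call. All stochastic
#' operations in the package route through this helper so that a single
#' integer seed fixes every draw without clobbering the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# full-precision numeric formatting used by every writer so that
# write -> read round-trips reproduce doubles exactly
format_full <- function(x) sprintf("%.17g", x)

stop_ <- function(...) stop(..., call. = FALSE)
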