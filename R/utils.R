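#' Derive a reproducible substream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' master seed and a stage name, so stages can be rerun independently and no
#' stage consumes another stage's random numbers.
#'
#' @param master_seed Integer master seed.
#' @param name Character stage name (e.g. `"cohort"`, `"fit"`).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "cohort")
substream_seed <- function(master_seed, name) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(name), length(name) == 1L)
  # deterministic string hash (polynomial rolling, modular arithmetic kept
  # in double-precision-exact range)
  h <- (master_seed %% 2147483647)
  for (cp in utf8ToInt(name)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's random number stream.
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  expr
}

# shared column order for trial tables written to disk
trial_cols <- c("subject", "condition", "phase", "block", "trial_index",
                "left_symbol", "right_symbol", "chosen", "outcome",
                "reward", "optimal")

task_phases <- c("practice", "learning", "choice0", "choice30", "choice24h")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
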