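# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

ll_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "lifelimits_error"),
                      call = sys.call(-1)))
}

ll_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "lifelimits_warning"),
                           call = sys.call(-1)))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (needed so that seeded callers
# can compose seedless building blocks deterministically).
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a run-level seed
#'
#' Stable string hash of the stage name folded into the run seed, so that
#' adding a stage to a pipeline never perturbs the random draws of the
#' others. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer run-level seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "panel") != derive_seed(1, "rounding")
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L,
            is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# round-half-away-from-zero / round-half-to-even on non-negative values
round_ties <- function(x, ties = c("away", "even")) {
  ties <- match.arg(ties)
  if (ties == "away") sign(x) * floor(abs(x) + 0.5) else round(x)
}
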