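#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the pipeline flows from a single master seed; each stage
#' (mask generation, decay simulation, fold assignment, weight initialisation,
#' minibatch shuffling, dropout) draws from a seed derived deterministically
#' from the master seed and the stage name, so stages are independently
#' reproducible.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # simple deterministic string hash (polynomial rolling, 31-bit)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

abort_glia <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gliastate_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
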