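#' seizr: EEG seizure classification with augmentation, fuzzy features and
#' swarm-tuned LSTM networks
#'
#' See the package vignette for the scientific background and the design
#' rationale of each stage.
#'
#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All randomness in the package is
# routed through `with_rng()` so that no function disturbs (or depends on)
# the caller's global RNG stream.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a private, seeded RNG stream
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `expr`, and restores the previous state on exit. Guarantees that
#' identical seeds give identical results and that callers never observe a
#' side effect on the global stream.
#'
#' @param seed integer scalar seed (must be finite, < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a child seed from a parent seed and a stream label; keeps all
# derived seeds strictly below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563)
}

stop_seizr <- function(msg, class, ...) {
  stop(structure(class = c(class, "seizr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

assert_that <- function(ok, msg, class = "seizr_invalid") {
  if (!isTRUE(ok)) stop_seizr(msg, class)
  invisible(TRUE)
}
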