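# Internal helpers shared across modules.

# Probabilities are clamped to .log_eps before taking logs inside energy and
# entropy computations; kl_divergence() alone is allowed to return +Inf.
.log_eps <- 1e-16

clamp_log <- function(p) log(pmax(p, .log_eps))

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards, so seeded generators behave as pure functions of
#' their arguments.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# One multinomial draw from a named probability vector; returns the label.
# Every stochastic choice in the package goes through this helper so that
# independently coded simulation loops can reproduce trajectories exactly.
sample_categorical <- function(probs) {
  stopifnot(!is.null(names(probs)))
  names(probs)[sample.int(length(probs), 1L, prob = probs)]
}

assert_labels <- function(labels, what = "labels") {
  if (length(labels) == 0L) stop(what, " must be non-empty", call. = FALSE)
  if (!is.character(labels)) stop(what, " must be character", call. = FALSE)
  if (anyDuplicated(labels)) stop(what, " must be unique", call. = FALSE)
  invisible(labels)
}
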