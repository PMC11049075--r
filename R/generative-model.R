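#' Discrete POMDP generative model
#'
#' The standard discrete active-inference model over finite state,
#' observation, and action sets:
#' \describe{
#'   \item{A}{likelihood `P(o | s)`, observations x states, column-stochastic}
#'   \item{B}{transitions `P(s' | s, u)`, one states x states map per action}
#'   \item{C}{preferences over observations, a categorical `P(o | c)`
#'     (log-preferences enter the risk and expected-value terms)}
#'   \item{D}{prior over initial hidden states}
#'   \item{E}{habit: prior over actions}
#'   \item{gamma}{precision of action selection}
#' }
#' Label sets are inferred from dimnames and must be mutually consistent.
#'
#' @param A Stochastic map states ~> observations (see [stoch_map()]).
#' @param B Named list per action of stochastic maps states ~> states.
#' @param C Categorical over observations (normalized preferences). Use
#'   [preferences_from_log()] to build one from unnormalized log-preferences.
#' @param D Categorical over states.
#' @param E Categorical over actions; defaults to uniform.
#' @param gamma Non-negative precision (default 1).
#' @return An object of class `"generative_model"`.
#' @export
generative_model <- function(A, B, C, D, E = NULL, gamma = 1) {
  validate_stoch_map(A, "A (likelihood)")
  obs <- rownames(A)
  states <- colnames(A)
  if (!is.list(B) || is.null(names(B))) {
    stop("B must be a named list of per-action transition maps", call. = FALSE)
  }
  actions <- names(B)
  assert_labels(actions, "actions")
  for (u in actions) {
    validate_stoch_map(B[[u]], paste0("B[['", u, "']]"))
    if (!identical(rownames(B[[u]]), states) || !identical(colnames(B[[u]]), states)) {
      stop("B[['", u, "']] must be states x states with the labels of A", call. = FALSE)
    }
  }
  if (is.null(E)) E <- categorical(rep(1, length(actions)), actions)
  C <- categorical(C, names(C) %||% obs, normalize = TRUE)
  D <- categorical(D, names(D) %||% states, normalize = TRUE)
  check_same_support(C, stats::setNames(numeric(length(obs)), obs))
  check_same_support(D, stats::setNames(numeric(length(states)), states))
  E <- categorical(E, names(E) %||% actions, normalize = TRUE)
  check_same_support(E, stats::setNames(numeric(length(actions)), actions))
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(states = states, obs = obs, actions = actions,
    A = A, B = B, C = C, D = D, E = E, gamma = gamma),
    class = "generative_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model> ", length(x$states), " states, ", length(x$obs),
    " observations, ", length(x$actions), " actions, gamma = ", x$gamma,
    "\n", sep = "")
  invisible(x)
}

#' Normalized preferences from log-preferences
#'
#' Maps unnormalized log-preferences (e.g. +3 on a rewarding observation,
#' negative on an aversive one, 0 elsewhere) to the categorical preference
#' vector `C` by exponentiation and normalization.
#'
#' @param logC Named numeric vector of log-preferences over observations.
#' @return A categorical vector.
#' @export
preferences_from_log <- function(logC) {
  categorical(exp(logC - max(logC)), names(logC))
}

#' Exact Bayesian state posterior
#'
#' The optimum of the variational problem on a finite state space: the
#' divergence term of the free energy vanishes there, so the posterior is
#' plain Bayes, `q(s)` proportional to `A(o | s) * prior(s)`.
#'
#' @param model A [generative_model()].
#' @param prior Categorical over states.
#' @param o Observation label.
#' @return Categorical posterior over states.
#' @export
exact_posterior <- function(model, prior, o) {
  if (!o %in% model$obs) stop("unknown observation '", o, "'", call. = FALSE)
  check_same_support(prior, model$D)
  w <- model$A[o, ] * prior
  if (sum(w) <= 0) {
    stop("observation '", o, "' has zero marginal likelihood under this prior",
      call. = FALSE)
  }
  categorical(w, model$states)
}

#' Variational free energy of a belief
#'
#' For a candidate belief `q` over states, prior `prior` and observation `o`:
#' `F = E_q[ln q(s) - ln A(o|s) - ln prior(s)]`, reported together with its
#' two standard decompositions, divergence-minus-log-evidence and
#' complexity-minus-accuracy. `F` upper-bounds the negative log evidence,
#' with equality exactly at the Bayesian posterior.
#'
#' @inheritParams exact_posterior
#' @param q Candidate categorical belief over states.
#' @return An object of class `"free_energy_report"` with fields `F`,
#'   `divergence`, `log_evidence`, `complexity`, `accuracy`.
#' @export
free_energy <- function(model, q, prior, o) {
  if (!o %in% model$obs) stop("unknown observation '", o, "'", call. = FALSE)
  check_same_support(q, model$D)
  check_same_support(prior, model$D)
  lik <- model$A[o, ]
  pos <- q > 0
  e_lnq <- sum(q[pos] * log(q[pos]))
  accuracy <- sum(q * clamp_log(lik))
  complexity <- e_lnq - sum(q[pos] * clamp_log(prior)[pos])
  log_evidence <- log(sum(lik * prior))
  post <- exact_posterior(model, prior, o)
  divergence <- e_lnq - sum(q[pos] * clamp_log(post)[pos])
  structure(list(
    F = complexity - accuracy,
    divergence = divergence, log_evidence = log_evidence,
    complexity = complexity, accuracy = accuracy),
    class = "free_energy_report")
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat(sprintf(
    "<free_energy> F = %.6f (divergence %.6f - log evidence %.6f; complexity %.6f - accuracy %.6f)\n",
    x$F, x$divergence, x$log_evidence, x$complexity, x$accuracy))
  invisible(x)
}
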