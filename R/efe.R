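#' Expected free energy of a predicted state distribution
#'
#' For the one-step predicted state distribution `q_next` under a candidate
#' action (i.e. `B_u %*% q`), computes the expected free energy
#' `G = risk + ambiguity`, where risk is the divergence of predicted from
#' preferred outcomes, `KL[q(o|u) || C]`, and ambiguity is the expected
#' outcome entropy `E_q[H[A(.|s)]]`. The report also carries the equivalent
#' epistemic/pragmatic split: `G = -info_gain - expected_value`, with the
#' information gain taken as the expected divergence between the exact
#' Bayesian state posterior under each predicted observation and `q_next`
#' (the predictive joint is `Q(o, s | u) = A(o|s) q_next(s)`, which makes
#' the two decompositions agree identically).
#'
#' @param model A [generative_model()].
#' @param q_next Categorical over states: the predicted state distribution.
#' @return An object of class `"efe_report"` with fields `G`, `risk`,
#'   `ambiguity`, `info_gain`, `expected_value`, and the predicted
#'   observation distribution `q_obs`. `risk` is `+Inf` when preferences put
#'   zero mass on a predicted observation (flagged, not fatal).
#' @export
expected_free_energy <- function(model, q_next) {
  check_same_support(q_next, model$D)
  q_obs <- categorical(as.vector(model$A %*% q_next), model$obs)
  risk <- kl_divergence(q_obs, model$C)
  ambiguity <- sum(q_next * apply(model$A, 2L, entropy_categorical))
  info_gain <- 0
  for (o in model$obs) {
    if (q_obs[[o]] <= 0) next
    post <- categorical(model$A[o, ] * q_next, model$states)
    pos <- post > 0
    info_gain <- info_gain +
      q_obs[[o]] * sum(post[pos] * (log(post[pos]) - clamp_log(q_next)[pos]))
  }
  expected_value <- sum(q_obs * clamp_log(model$C))
  structure(list(G = risk + ambiguity, risk = risk, ambiguity = ambiguity,
    info_gain = info_gain, expected_value = expected_value, q_obs = q_obs),
    class = "efe_report")
}

#' @export
print.efe_report <- function(x, ...) {
  cat(sprintf(
    "<efe> G = %.6f (risk %.6f + ambiguity %.6f; info gain %.6f, expected value %.6f)\n",
    x$G, x$risk, x$ambiguity, x$info_gain, x$expected_value))
  invisible(x)
}

# Expected free energy for every action from a current belief.
efe_per_action <- function(model, belief, actions = model$actions) {
  vapply(actions, function(u) {
    expected_free_energy(model, categorical(
      as.vector(model$B[[u]] %*% belief), model$states))$G
  }, numeric(1))
}

#' Posterior over actions from expected free energies
#'
#' `P(u) = sigma(ln E - gamma * G(u))`: the habit prior `E` enters as a log
#' bias, so with a uniform habit this reduces exactly to the softmax of
#' negated, precision-scaled expected free energy.
#'
#' @param model A [generative_model()] (supplies `E` and `gamma`).
#' @param efe Named numeric vector of finite expected free energies, one per
#'   action of the model.
#' @return Categorical over actions.
#' @export
action_posterior <- function(model, efe) {
  if (!identical(sort(names(efe)), sort(model$actions))) {
    stop("efe must carry one value per action", call. = FALSE)
  }
  efe <- efe[model$actions]
  if (any(!is.finite(efe))) stop("expected free energies must be finite", call. = FALSE)
  z <- clamp_log(model$E) - model$gamma * efe
  z <- z - max(z)
  w <- exp(z)
  categorical(w, model$actions)
}

#' Depth-limited policy evaluation
#'
#' Enumerates all action sequences of the given depth and accumulates
#' expected free energy additively along each, propagating the predicted
#' state distribution marginally through `B` (no observation conditioning
#' within the rollout). Depth 1 reduces to per-action expected free energy.
#'
#' @param model A [generative_model()].
#' @param q Current categorical belief over states.
#' @param depth Policy depth (>= 1).
#' @param cap Maximum number of policies (`|U|^depth`) to enumerate.
#' @return A data frame with columns `policy` (actions joined by spaces),
#'   `G` (cumulative expected free energy) and `prior` (product of habit
#'   weights along the sequence).
#' @export
rollout_policies <- function(model, q, depth, cap = 1e5) {
  stopifnot(depth >= 1)
  n_pol <- length(model$actions)^depth
  if (n_pol > cap) {
    stop("policy count ", n_pol, " exceeds cap ", cap, call. = FALSE)
  }
  grid <- expand.grid(rep(list(model$actions), depth),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  G <- numeric(n_pol)
  prior <- numeric(n_pol)
  for (r in seq_len(n_pol)) {
    acts <- as.character(grid[r, ])
    qc <- q
    g <- 0
    for (u in acts) {
      qc <- categorical(as.vector(model$B[[u]] %*% qc), model$states)
      g <- g + expected_free_energy(model, qc)$G
    }
    G[r] <- g
    prior[r] <- prod(model$E[acts])
  }
  data.frame(policy = apply(grid, 1L, paste, collapse = " "),
    G = G, prior = prior, stringsAsFactors = FALSE)
}

#' One perception-action cycle of a single agent
#'
#' Loop order: observe -> infer (exact Bayes) -> evaluate expected free
#' energy per action -> act (sample from the action posterior) -> propagate
#' the prior for the next step through the chosen action's transitions.
#'
#' @param model A [generative_model()].
#' @param belief Categorical prior over states (before observing).
#' @param o Observation label.
#' @param seed Optional seed for the action draw.
#' @return List with `belief` (posterior), `action`, `next_prior`,
#'   `free_energy` (a [free_energy()] report at the posterior), `efe`
#'   (named numeric per action) and `action_posterior`.
#' @export
agent_step <- function(model, belief, o, seed = NULL) {
  with_seed(seed, {
    post <- exact_posterior(model, belief, o)
    fe <- free_energy(model, post, belief, o)
    G <- efe_per_action(model, post)
    ap <- action_posterior(model, G)
    action <- sample_categorical(ap)
    next_prior <- categorical(as.vector(model$B[[action]] %*% post), model$states)
    list(belief = post, action = action, next_prior = next_prior,
      free_energy = fe, efe = G, action_posterior = ap)
  })
}

#' POMDP as a dynamical system on the monomial interface O y^U
#'
#' Repackages a generative model as a [dynamical_system()]: positions are
#' observations (emitted stochastically from the likelihood `A`), directions
#' are actions, and the per-state updates apply the transition maps `B`.
#' The tables round-trip exactly through [stoch_poly_tables()].
#'
#' @param model A [generative_model()].
#' @return A `dynamical_system` over `make_monomial(observations, actions)`.
#' @export
to_stoch_poly <- function(model) {
  iface <- make_monomial(model$obs, model$actions)
  update <- lapply(model$states, function(s) {
    m <- vapply(model$actions, function(u) model$B[[u]][, s], numeric(length(model$states)))
    stoch_map(m, from = model$actions, to = model$states)
  })
  names(update) <- model$states
  dynamical_system(model$states, iface, output = model$A, update = update)
}

#' Read POMDP tables back out of a dynamical system
#'
#' Inverse of [to_stoch_poly()]: recovers the likelihood `A` and the
#' per-action transition maps `B`.
#'
#' @param sys A `dynamical_system` produced by [to_stoch_poly()].
#' @return List with elements `A` and `B`.
#' @export
stoch_poly_tables <- function(sys) {
  stopifnot(inherits(sys, "dynamical_system"), is.matrix(sys$output))
  actions <- sys$interface$directions[[1L]]
  states <- sys$states
  B <- lapply(actions, function(u) {
    m <- vapply(states, function(s) sys$update[[s]][, u], numeric(length(states)))
    stoch_map(m, from = states, to = states)
  })
  names(B) <- actions
  list(A = sys$output, B = B)
}
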