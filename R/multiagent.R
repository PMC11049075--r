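#' Joint action labels for an ensemble
#'
#' Joint actions are labelled by joining each agent's own action with `"|"`
#' in agent order (first agent's component varies fastest), matching the
#' pair-label convention of [poly_tensor()].
#'
#' @param action_sets Named list (agent id -> character vector of own actions).
#' @return Character vector of joint action labels.
#' @export
joint_action_labels <- function(action_sets) {
  stopifnot(is.list(action_sets), !is.null(names(action_sets)))
  grid <- expand.grid(action_sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "|")
}

split_joint_action <- function(label) strsplit(label, "|", fixed = TRUE)

#' Agent specification for ensemble simulation
#'
#' An agent in a group holds a generative model over the *joint* interface:
#' its observation set is its own, but its action set is the product of all
#' agents' actions (labels as in [joint_action_labels()]), because it
#' believes the hidden dynamics depend on everyone's actions. Its boundary
#' interface is the monomial over its own observations and own actions.
#'
#' @param id Agent identifier.
#' @param model A [generative_model()] whose actions are joint labels.
#' @param own_actions This agent's own action labels.
#' @param tom_depth Depth of recursive modelling of companions (>= 0):
#'   0 predicts others from their habit only, `d >= 1` simulates their
#'   action selection with depth `d - 1` predictions of everyone else.
#' @return An object of class `"agent_spec"`.
#' @export
agent_spec <- function(id, model, own_actions, tom_depth = 1) {
  stopifnot(inherits(model, "generative_model"))
  assert_labels(own_actions, "own actions")
  if (tom_depth < 0) stop("tom_depth must be >= 0", call. = FALSE)
  structure(list(id = id, model = model, own_actions = own_actions,
    tom_depth = tom_depth,
    interface = make_monomial(model$obs, own_actions)),
    class = "agent_spec")
}

#' Joint interface of an ensemble
#'
#' The tensor of all agents' boundary interfaces: positions are joint
#' configurations, directions joint sense data.
#'
#' @param agents List of [agent_spec()] objects.
#' @return A `polynomial`.
#' @export
build_joint_interface <- function(agents) {
  stopifnot(length(agents) >= 1L)
  Reduce(poly_tensor, lapply(agents, `[[`, "interface"))
}

#' Ground-truth world for an ensemble
#'
#' @param states Character state labels of the shared environment.
#' @param channels Named list (agent id -> stochastic map states ~>
#'   that agent's observations): per-agent observation channels.
#' @param B Named list (joint action label -> states x states stochastic
#'   map): joint transition kernel.
#' @param init Categorical over states: initial state distribution.
#' @return An object of class `"world_env"`.
#' @export
world_env <- function(states, channels, B, init) {
  assert_labels(states, "states")
  for (j in names(channels)) {
    validate_stoch_map(channels[[j]], paste0("channel '", j, "'"))
    if (!identical(colnames(channels[[j]]), states)) {
      stop("channel '", j, "' must be conditioned on the world states", call. = FALSE)
    }
  }
  for (u in names(B)) {
    validate_stoch_map(B[[u]], paste0("world B[['", u, "']]"))
  }
  init <- categorical(init, names(init) %||% states)
  check_same_support(init, stats::setNames(numeric(length(states)), states))
  structure(list(states = states, channels = channels, B = B, init = init),
    class = "world_env")
}

# Marginalize a distribution over joint-action labels onto one agent's own
# actions.
marginal_own <- function(dist_joint, agent_idx, own_actions) {
  comps <- vapply(split_joint_action(names(dist_joint)), `[[`, character(1), agent_idx)
  out <- vapply(own_actions, function(a) sum(dist_joint[comps == a]), numeric(1))
  categorical(out, own_actions)
}

# Expected free energy of one agent for every joint action.
efe_by_joint <- function(model, belief) {
  efe_per_action(model, belief)
}

# Marginal EFE over own actions, weighting joint actions by predicted
# distributions over the other agents' actions.
marginal_efe <- function(G_joint, agent_idx, own_actions, predictions) {
  comps <- do.call(rbind, split_joint_action(names(G_joint)))
  out <- numeric(length(own_actions))
  names(out) <- own_actions
  for (a in own_actions) {
    sel <- comps[, agent_idx] == a
    w <- rep(1, sum(sel))
    for (m in names(predictions)) {
      midx <- as.integer(m)
      w <- w * predictions[[m]][comps[sel, midx]]
    }
    out[[a]] <- sum(w * G_joint[sel])
  }
  out
}

# Own-action selection: marginal EFE plus the softmax posterior
# sigma(ln E_own - gamma * G_own).
own_action_select <- function(agent, agent_idx, belief, predictions) {
  model <- agent$model
  if (length(predictions) == 0L &&
      identical(sort(agent$own_actions), sort(model$actions))) {
    # single agent: joint = own; identical code path to agent_step()
    G <- efe_per_action(model, belief)
    return(list(posterior = action_posterior(model, G), G = G))
  }
  E_own <- marginal_own(model$E, agent_idx, agent$own_actions)
  G_joint <- efe_by_joint(model, belief)
  G_own <- marginal_efe(G_joint, agent_idx, agent$own_actions, predictions)
  z <- clamp_log(E_own) - model$gamma * G_own
  z <- z - max(z)
  list(posterior = categorical(exp(z), agent$own_actions), G = G_own)
}

own_action_posterior <- function(agent, agent_idx, belief, predictions) {
  own_action_select(agent, agent_idx, belief, predictions)$posterior
}

#' Predict another agent's action distribution
#'
#' Recursive theory of mind under the shared-model assumption: the
#' predicting agent holds a veridical copy of the other's model and uses its
#' own current posterior as its estimate of the other's information state.
#' At depth 0 the prediction is the other's habit (marginalized onto its own
#' actions); at depth `d >= 1` the other's action selection is simulated
#' with depth `d - 1` predictions of everyone else.
#'
#' @param agents List of [agent_spec()] objects (the ensemble).
#' @param j Index of the predicting agent.
#' @param k Index of the agent being predicted.
#' @param belief The predicting agent's categorical belief over states.
#' @param depth Recursion depth; defaults to agent `j`'s `tom_depth`.
#' @return Categorical over agent `k`'s own actions.
#' @export
predict_other <- function(agents, j, k, belief, depth = agents[[j]]$tom_depth) {
  other <- agents[[k]]
  if (depth <= 0L) {
    return(marginal_own(other$model$E, k, other$own_actions))
  }
  preds <- list()
  for (m in seq_along(agents)) {
    if (m == k) next
    preds[[as.character(m)]] <-
      predict_other(agents, k, m, belief, depth = depth - 1L)
  }
  own_action_posterior(other, k, belief, preds)
}

#' Simulate an ensemble of active-inference agents in a shared world
#'
#' Per step, in agent order: each agent observes through its channel, does
#' exact Bayesian inference, predicts its companions' actions
#' ([predict_other()]), marginalizes its joint-action expected free energy
#' over those predictions, and samples its own action; the world then
#' transitions on the realized joint action, and each agent propagates its
#' prior through its transition model, averaging over its predictions of the
#' others. With a single agent this reduces exactly (same seed, same draws)
#' to the [agent_step()] loop.
#'
#' @param env A [world_env()].
#' @param agents List of [agent_spec()], in the order of the env channels.
#' @param T Number of steps (>= 1).
#' @param seed Optional integer seed.
#' @return An object of class `"ensemble_trajectory"`: lists of per-step
#'   states, observations, beliefs, actions, predictions and free energies.
#' @export
simulate_ensemble <- function(env, agents, T, seed = NULL) {
  stopifnot(inherits(env, "world_env"), T >= 1)
  n <- length(agents)
  ids <- vapply(agents, `[[`, character(1), "id")
  if (!identical(ids, names(env$channels))) {
    stop("agents and env channels must list the same ids in the same order",
      call. = FALSE)
  }
  joint_labels <- joint_action_labels(
    stats::setNames(lapply(agents, `[[`, "own_actions"), ids))
  for (ag in agents) {
    if (!identical(sort(ag$model$actions), sort(joint_labels))) {
      stop("agent '", ag$id, "' does not model the joint action set", call. = FALSE)
    }
    if (!identical(sort(ag$model$obs), sort(rownames(env$channels[[ag$id]])))) {
      stop("agent '", ag$id, "' observation set does not match its channel",
        call. = FALSE)
    }
  }
  if (!identical(sort(names(env$B)), sort(joint_labels))) {
    stop("world transition kernel must cover every joint action", call. = FALSE)
  }
  with_seed(seed, {
    s <- sample_categorical(env$init)
    priors <- lapply(agents, function(ag) ag$model$D)
    states <- character(T)
    obs <- matrix("", T, n, dimnames = list(NULL, ids))
    actions <- matrix("", T, n, dimnames = list(NULL, ids))
    Fmat <- matrix(NA_real_, T, n, dimnames = list(NULL, ids))
    beliefs <- vector("list", T)
    preds <- vector("list", T)
    efes <- vector("list", T)
    for (t in seq_len(T)) {
      states[t] <- s
      for (j in seq_len(n)) {
        obs[t, j] <- sample_categorical(env$channels[[j]][, s])
      }
      posts <- vector("list", n)
      step_preds <- vector("list", n)
      for (j in seq_len(n)) {
        ag <- agents[[j]]
        posts[[j]] <- exact_posterior(ag$model, priors[[j]], obs[t, j])
        Fmat[t, j] <- free_energy(ag$model, posts[[j]], priors[[j]], obs[t, j])$F
        pj <- list()
        for (k in seq_len(n)) {
          if (k == j) next
          pj[[as.character(k)]] <- predict_other(agents, j, k, posts[[j]])
        }
        step_preds[[j]] <- pj
      }
      step_G <- vector("list", n)
      for (j in seq_len(n)) {
        sel <- own_action_select(agents[[j]], j, posts[[j]], step_preds[[j]])
        step_G[[j]] <- sel$G
        actions[t, j] <- sample_categorical(sel$posterior)
      }
      joint <- paste(actions[t, ], collapse = "|")
      s <- sample_categorical(env$B[[joint]][, s])
      for (j in seq_len(n)) {
        ag <- agents[[j]]
        if (n == 1L) {
          priors[[j]] <- categorical(
            as.vector(ag$model$B[[joint]] %*% posts[[j]]), ag$model$states)
        } else {
          # average the transition over predicted companion actions, with
          # the agent's own realized action fixed
          comps <- do.call(rbind, split_joint_action(ag$model$actions))
          sel <- which(comps[, j] == actions[t, j])
          acc <- numeric(length(ag$model$states))
          for (idx in sel) {
            w <- 1
            for (m in names(step_preds[[j]])) {
              w <- w * step_preds[[j]][[m]][comps[idx, as.integer(m)]]
            }
            acc <- acc + w * as.vector(ag$model$B[[ag$model$actions[idx]]] %*% posts[[j]])
          }
          priors[[j]] <- categorical(acc, ag$model$states)
        }
      }
      beliefs[[t]] <- posts
      preds[[t]] <- step_preds
      efes[[t]] <- step_G
    }
    structure(list(ids = ids, states = states, obs = obs, actions = actions,
      beliefs = beliefs, predictions = preds, G = efes, F = Fmat, T = T),
      class = "ensemble_trajectory")
  })
}

#' @export
print.ensemble_trajectory <- function(x, ...) {
  cat("<ensemble_trajectory> ", length(x$ids), " agent(s), ", x$T, " step(s)\n",
    sep = "")
  invisible(x)
}

#' Per-step synchrony metrics of an ensemble trajectory
#'
#' Computes, per step: the mean pairwise symmetrized KL divergence between
#' agents' posterior beliefs (declining divergence operationalizes
#' generalized synchrony); the mean log-score of each agent's prediction of
#' the others' realized actions (0 only under deterministic correct
#' prediction, otherwise negative); and the summed variational free energy
#' across agents (a joint free-energy proxy).
#'
#' @param traj An [simulate_ensemble()] trajectory with at least two agents.
#' @return A data frame with columns `step`, `mean_belief_kl`,
#'   `mean_log_score`, `total_F`.
#' @export
synchrony_trace <- function(traj) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  n <- length(traj$ids)
  if (n < 2L) stop("synchrony metrics need at least two agents", call. = FALSE)
  out <- data.frame(step = seq_len(traj$T), mean_belief_kl = NA_real_,
    mean_log_score = NA_real_, total_F = rowSums(traj$F))
  for (t in seq_len(traj$T)) {
    kls <- c()
    scores <- c()
    for (j in seq_len(n - 1L)) {
      for (k in (j + 1L):n) {
        qj <- traj$beliefs[[t]][[j]]
        qk <- traj$beliefs[[t]][[k]]
        kls <- c(kls, 0.5 * (kl_divergence(qj, qk) + kl_divergence(qk, qj)))
      }
    }
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (k == j) next
        pred <- traj$predictions[[t]][[j]][[as.character(k)]]
        scores <- c(scores, clamp_log(pred)[[traj$actions[t, k]]])
      }
    }
    out$mean_belief_kl[t] <- mean(kls)
    out$mean_log_score[t] <- mean(scores)
  }
  out
}
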