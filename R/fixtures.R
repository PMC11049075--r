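# Seeded scenario generators. Every generator is a pure function of its
# parameters and seed (the caller's RNG state is preserved), so repeated
# calls are byte-identical.

# Dirichlet draw via normalized gamma variates.
rdirichlet1 <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  if (sum(g) <= 0) g <- rep(1, n) # pathological underflow guard
  g / sum(g)
}

rand_stoch_map <- function(from, to, concentration) {
  m <- vapply(from, function(x) rdirichlet1(length(to), concentration),
    numeric(length(to)))
  stoch_map(m, from = from, to = to)
}

#' Random well-formed generative model
#'
#' Columns of A, B and the C, D, E vectors are drawn from symmetric
#' Dirichlet distributions with the given concentration (small values give
#' peaked, informative tables; very large values give near-uniform ones).
#'
#' @param n_states,n_obs,n_actions Positive dimensions.
#' @param concentration Positive Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @param gamma Action precision of the generated model.
#' @return A [generative_model()].
#' @export
random_model <- function(n_states, n_obs, n_actions, concentration = 1,
                         seed = 1, gamma = 1) {
  stopifnot(n_states >= 1, n_obs >= 1, n_actions >= 1, concentration > 0)
  with_seed(seed, {
    states <- paste0("s", seq_len(n_states))
    obs <- paste0("o", seq_len(n_obs))
    actions <- paste0("u", seq_len(n_actions))
    A <- rand_stoch_map(states, obs, concentration)
    B <- lapply(actions, function(u) rand_stoch_map(states, states, concentration))
    names(B) <- actions
    C <- categorical(rdirichlet1(n_obs, concentration), obs)
    D <- categorical(rdirichlet1(n_states, concentration), states)
    E <- categorical(rdirichlet1(n_actions, concentration), actions)
    generative_model(A, B, C, D, E, gamma = gamma)
  })
}

#' T-maze epistemic-foraging scenario
#'
#' A four-location maze (center junction, left arm, right arm, cue site)
#' crossed with two latent reward contexts (reward on the left or on the
#' right), giving eight hidden states. The cue observation reveals the
#' context with probability `cue_accuracy` and is available only at the cue
#' site; the arms deterministically yield a rewarding or aversive
#' observation depending on the context and are absorbing; reading the cue
#' bounces the agent back to the junction unless it commits to an arm.
#' Preferences are neutral away from the arms (log-preference +3 on the
#' reward, -4 on the loss), so the value of visiting the cue is purely
#' epistemic: exhaustive depth-2 policy evaluation ranks cue-then-arm
#' policies strictly below every policy that does not visit the cue first.
#'
#' @param cue_accuracy Probability in (0.5, 1] that the cue indicates the
#'   true context (default 0.98).
#' @param seed Integer seed (used for the world's initial context draw in
#'   simulation; the model itself is deterministic).
#' @param reward_logC,loss_logC Log-preferences of the reward and loss
#'   observations.
#' @return A scenario bundle: list with `env` ([world_env()]), `agents`
#'   (one [agent_spec()]), `model`, `cover`, `sections`, `site_assignment`,
#'   `admissibility`, and `metadata`.
#' @export
make_tmaze <- function(cue_accuracy = 0.98, seed = 1,
                       reward_logC = 3, loss_logC = -4) {
  if (cue_accuracy <= 0.5 || cue_accuracy > 1) {
    stop("cue_accuracy must lie in (0.5, 1]", call. = FALSE)
  }
  locs <- c("center", "left", "right", "cue")
  ctx <- c("L", "R")
  states <- as.vector(outer(locs, ctx, paste, sep = "."))
  obs <- c("start", "cue-left", "cue-right", "reward", "loss")
  actions <- c("go-center", "go-left", "go-right", "go-cue")
  a <- cue_accuracy

  A <- matrix(0, length(obs), length(states), dimnames = list(obs, states))
  for (cc in ctx) {
    A["start", paste0("center.", cc)] <- 1
    A["cue-left", paste0("cue.", cc)] <- if (cc == "L") a else 1 - a
    A["cue-right", paste0("cue.", cc)] <- if (cc == "R") a else 1 - a
    A["reward", paste0("left.", cc)] <- if (cc == "L") 1 else 0
    A["loss", paste0("left.", cc)] <- if (cc == "L") 0 else 1
    A["reward", paste0("right.", cc)] <- if (cc == "R") 1 else 0
    A["loss", paste0("right.", cc)] <- if (cc == "R") 0 else 1
  }
  A <- stoch_map(A)

  move <- function(from, u) {
    if (from %in% c("left", "right")) return(from) # arms absorb
    if (from == "cue") {
      return(switch(u, "go-left" = "left", "go-right" = "right", "center"))
    }
    switch(u, "go-center" = "center", "go-left" = "left",
      "go-right" = "right", "go-cue" = "cue")
  }
  B <- lapply(actions, function(u) {
    m <- matrix(0, length(states), length(states), dimnames = list(states, states))
    for (cc in ctx) for (l in locs) {
      m[paste0(move(l, u), ".", cc), paste0(l, ".", cc)] <- 1
    }
    stoch_map(m)
  })
  names(B) <- actions

  logC <- stats::setNames(numeric(length(obs)), obs)
  logC[["reward"]] <- reward_logC
  logC[["loss"]] <- loss_logC
  C <- preferences_from_log(logC)
  D <- categorical(stats::setNames(as.numeric(states %in% c("center.L", "center.R")),
    states))
  model <- generative_model(A, B, C, D, gamma = 1)

  env <- world_env(states, channels = list(ant = A), B = B, init = D)
  agents <- list(agent_spec("ant", model, own_actions = actions, tom_depth = 0))
  site_assignment <- stats::setNames(sub("\\..*$", "", states), states)
  admissibility <- list(center = "start", cue = c("cue-left", "cue-right"),
    left = c("reward", "loss"), right = c("reward", "loss"))
  cov <- cover(locs, patches = list(ant = locs))
  sections <- list(ant = section("ant", stats::setNames(
    rep(list(categorical(c(L = 0.5, R = 0.5))), length(locs)), locs)))
  list(env = env, agents = agents, model = model, cover = cov,
    sections = sections, site_assignment = site_assignment,
    admissibility = admissibility,
    metadata = list(generator = "make_tmaze", cue_accuracy = cue_accuracy,
      reward_logC = reward_logC, loss_logC = loss_logC, seed = seed))
}

#' Shared-world cover with controllable disagreement
#'
#' Builds a chained cover of `n_sites` sites by `n_agents` patches with the
#' given pairwise overlap, draws one consistent categorical vector per site
#' (so the restricted sections glue exactly), then perturbs each later
#' agent's vectors on its shared sites by exactly `epsilon` in total
#' variation. With `epsilon = 0` the sections glue at tolerance `1e-12`.
#'
#' @param n_agents,n_sites Positive counts.
#' @param overlap Number of sites shared by consecutive patches (>= 0).
#' @param epsilon Total-variation perturbation applied on overlaps (>= 0).
#' @param seed Integer seed.
#' @param dim Length of each site's categorical vector (default 3).
#' @return List with `cover`, `sections`, `truth` (the unperturbed global
#'   data) and `metadata`.
#' @export
make_shared_world <- function(n_agents, n_sites, overlap = 1, epsilon = 0,
                              seed = 1, dim = 3) {
  stopifnot(n_agents >= 1, n_sites >= 1, overlap >= 0, epsilon >= 0)
  base <- paste0("x", seq_len(n_sites))
  L <- ceiling((n_sites + (n_agents - 1) * overlap) / n_agents)
  if (n_agents > 1 && L <= overlap) {
    stop("impossible cover geometry: overlap ", overlap,
      " too large for ", n_sites, " sites and ", n_agents, " agents",
      call. = FALSE)
  }
  starts <- 1 + (seq_len(n_agents) - 1L) * (L - overlap)
  if (any(starts > n_sites)) {
    stop("impossible cover geometry: patches run past the base", call. = FALSE)
  }
  patches <- lapply(seq_len(n_agents), function(j) {
    base[starts[j]:min(starts[j] + L - 1L, n_sites)]
  })
  if (max(starts) + L - 1L < n_sites) {
    patches[[n_agents]] <- base[starts[n_agents]:n_sites]
  }
  names(patches) <- paste0("agent", seq_len(n_agents))
  cov <- cover(base, patches)

  with_seed(seed, {
    labels <- paste0("k", seq_len(dim))
    truth <- lapply(base, function(x) categorical(rdirichlet1(dim, 1), labels))
    names(truth) <- base
    sections <- lapply(names(patches), function(j) {
      section(j, truth[patches[[j]]])
    })
    names(sections) <- names(patches)
    if (epsilon > 0) {
      for (ov in cov$overlaps) {
        k <- ov$pair[2] # perturb the later agent of each pair, once per site
        for (site in ov$sites) {
          v <- sections[[k]]$data[[site]]
          hi <- which.max(v)
          lo <- which.min(v)
          if (v[hi] < epsilon || hi == lo) {
            stop("epsilon ", epsilon, " infeasible for site '", site, "'",
              call. = FALSE)
          }
          v[hi] <- v[hi] - epsilon
          v[lo] <- v[lo] + epsilon
          sections[[k]]$data[[site]] <- categorical(v, names(v), normalize = FALSE)
        }
      }
    }
    list(cover = cov, sections = sections, truth = truth,
      metadata = list(generator = "make_shared_world", n_agents = n_agents,
        n_sites = n_sites, overlap = overlap, epsilon = epsilon,
        seed = seed, dim = dim))
  })
}

#' Randomly perturb sections
#'
#' Mixes every site-vector with an independent random categorical vector at
#' weight `epsilon`: `v' = (1 - epsilon) v + epsilon r`. `epsilon = 0` is
#' the identity; `epsilon = 1` replaces the vectors outright. Starting from
#' consistent sections, the disagreement energy is non-decreasing in
#' `epsilon` for a fixed seed.
#'
#' @param sections Named list of [section()]s.
#' @param epsilon Mixing weight in \\[0, 1\\].
#' @param seed Integer seed.
#' @return The perturbed sections.
#' @export
perturb_sections <- function(sections, epsilon, seed = 1) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  with_seed(seed, {
    for (j in names(sections)) {
      for (site in names(sections[[j]]$data)) {
        v <- sections[[j]]$data[[site]]
        r <- categorical(rdirichlet1(length(v), 1), names(v))
        sections[[j]]$data[[site]] <-
          categorical((1 - epsilon) * v + epsilon * r, names(v))
      }
    }
    sections
  })
}

#' Shared-world ensemble scenario for synchrony experiments
#'
#' Two or more agents inhabit the same hidden-state process, observe it
#' through a shared informative channel (each agent draws its own
#' observation from the same conditional), and model the joint action set.
#' The scenario varies *only* the initial priors between agents: with
#' `divergent_priors` each agent's `D` is peaked (mass 0.9) on a different
#' state, so early disagreement is prior-driven, while late disagreement
#' only reflects independent per-step observation noise. Generalized
#' synchrony (declining pairwise belief divergence) requires an
#' identifiable, trackable world, so the channel maps every state to a
#' distinct preferred observation with probability `1 - noise` and the
#' hidden dynamics are sticky (see `persistence`).
#'
#' @param n_agents Number of agents (>= 1).
#' @param n_states,n_obs Dimensions of the shared world (`n_obs >=
#'   n_states`).
#' @param n_actions_each Own actions per agent.
#' @param noise Channel noise level in \\[0, 1) (default 0.1).
#' @param persistence Self-persistence of the hidden dynamics in \\[0, 1):
#'   each joint-action transition is `persistence * I + (1 - persistence) *`
#'   a random stochastic map (default 0.7). Slowly varying hidden states are
#'   what makes the shared world trackable over time; a world that
#'   decorrelates every step leaves nothing for beliefs to converge on.
#' @param divergent_priors Give each agent a prior peaked on a different
#'   state (default `TRUE`)?
#' @param seed Integer seed.
#' @param tom_depth Theory-of-mind depth for every agent.
#' @return List with `env` ([world_env()]), `agents` (list of
#'   [agent_spec()]), and `metadata`.
#' @export
make_ensemble <- function(n_agents = 2, n_states = 3, n_obs = 4,
                          n_actions_each = 2, noise = 0.1, persistence = 0.7,
                          divergent_priors = TRUE, seed = 1, tom_depth = 1) {
  stopifnot(n_agents >= 1, n_obs >= n_states, noise >= 0, noise < 1,
    persistence >= 0, persistence < 1)
  with_seed(seed, {
    states <- paste0("s", seq_len(n_states))
    obs <- paste0("o", seq_len(n_obs))
    ids <- paste0("agent", seq_len(n_agents))
    own <- lapply(ids, function(j) paste0("a", seq_len(n_actions_each)))
    names(own) <- ids
    joint <- joint_action_labels(own)
    pref <- sample(obs, n_states) # injection: state -> preferred obs
    shared_A <- matrix(noise / max(n_obs - 1L, 1L), n_obs, n_states,
      dimnames = list(obs, states))
    for (i in seq_len(n_states)) shared_A[pref[i], states[i]] <- 1 - noise
    shared_A <- stoch_map(shared_A)
    channels <- stats::setNames(rep(list(shared_A), n_agents), ids)
    B <- lapply(joint, function(u) {
      stoch_map(persistence * diag(n_states) +
        (1 - persistence) * rand_stoch_map(states, states, 1),
        from = states, to = states)
    })
    names(B) <- joint
    init <- categorical(rep(1, n_states), states)
    env <- world_env(states, channels, B, init)
    agents <- lapply(seq_len(n_agents), function(j) {
      D <- if (divergent_priors) {
        peak <- ((j - 1L) %% n_states) + 1L
        w <- rep(0.1 / max(n_states - 1L, 1L), n_states)
        w[peak] <- 0.9
        categorical(w, states)
      } else {
        categorical(rep(1, n_states), states)
      }
      model <- generative_model(A = channels[[j]], B = B,
        C = categorical(rep(1, n_obs), obs), D = D, gamma = 1)
      agent_spec(ids[j], model, own_actions = own[[j]], tom_depth = tom_depth)
    })
    list(env = env, agents = agents,
      metadata = list(generator = "make_ensemble", n_agents = n_agents,
        n_states = n_states, n_obs = n_obs, n_actions_each = n_actions_each,
        noise = noise, persistence = persistence,
        divergent_priors = divergent_priors, seed = seed,
        tom_depth = tom_depth))
  })
}
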