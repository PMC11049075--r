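#' Discrete dynamical systems on a polynomial interface
#'
#' A system with state space `S` and interface polynomial `p` consists of an
#' output map `S -> p(1)` choosing a configuration of the interface for every
#' state, and per-state update maps `p[output(s)] -> S` consuming the inputs
#' admissible in that configuration. Both components may be deterministic or
#' stochastic; stochastic feedback is represented by column-stochastic
#' matrices ([stoch_map()]).
#'
#' @param states Character vector of state labels.
#' @param interface A `polynomial`.
#' @param output Either a named character vector `state -> position`, or a
#'   column-stochastic matrix with positions in rows and states in columns
#'   (stochastic emission; requires a monomial interface so that the
#'   admissible inputs do not depend on the emitted configuration).
#' @param update Named list over states. Each element is either a named
#'   character vector `input -> next state` or a column-stochastic matrix
#'   with states in rows and inputs in columns.
#' @return An object of class `"dynamical_system"`.
#' @export
dynamical_system <- function(states, interface, output, update) {
  assert_labels(states, "states")
  stopifnot(inherits(interface, "polynomial"))
  stochastic_out <- is.matrix(output)
  if (stochastic_out) {
    validate_stoch_map(output, "output map")
    if (!identical(sort(rownames(output)), sort(interface$positions)) ||
        !identical(sort(colnames(output)), sort(states))) {
      stop("stochastic output must map states to interface positions", call. = FALSE)
    }
    sizes <- unique(lapply(interface$directions, sort))
    if (length(sizes) != 1L) {
      stop("stochastic output requires a monomial interface", call. = FALSE)
    }
  } else {
    if (!identical(sort(names(output)), sort(states)) ||
        !all(output %in% interface$positions)) {
      stop("output must be total from states to interface positions", call. = FALSE)
    }
  }
  if (!identical(sort(names(update)), sort(states))) {
    stop("update must be defined for every state", call. = FALSE)
  }
  for (s in states) {
    u <- update[[s]]
    dom <- if (stochastic_out) interface$directions[[1L]] else
      interface$directions[[output[[s]]]]
    if (is.matrix(u)) {
      validate_stoch_map(u, paste0("update at state '", s, "'"))
      ok <- identical(sort(colnames(u)), sort(dom)) &&
        identical(sort(rownames(u)), sort(states))
    } else {
      ok <- identical(sort(names(u)), sort(dom)) && all(u %in% states)
    }
    if (!ok) stop("update at state '", s, "' is not total on its inputs", call. = FALSE)
  }
  structure(list(states = states, interface = interface,
    output = output, update = update), class = "dynamical_system")
}

emit_config <- function(sys, s) {
  if (is.matrix(sys$output)) sample_categorical(sys$output[, s]) else
    sys$output[[s]]
}

#' Unroll a dynamical system over an input sequence
#'
#' At each step the system emits the configuration of its current state,
#' then consumes the next input (which must be admissible for that
#' configuration) to transition. The trajectory has `length(inputs) + 1`
#' rows; the final row emits a configuration but consumes no input.
#'
#' @param sys A [dynamical_system()].
#' @param inputs Character vector of inputs (directions).
#' @param s0 Initial state.
#' @param seed Optional integer seed for stochastic components.
#' @return A data frame with columns `step`, `state`, `config`.
#' @export
run_system <- function(sys, inputs, s0, seed = NULL) {
  stopifnot(inherits(sys, "dynamical_system"))
  if (!s0 %in% sys$states) stop("s0 must be a state of the system", call. = FALSE)
  with_seed(seed, {
    n <- length(inputs)
    state <- character(n + 1L)
    config <- character(n + 1L)
    s <- s0
    for (t in seq_len(n + 1L)) {
      state[t] <- s
      cfg <- emit_config(sys, s)
      config[t] <- cfg
      if (t > n) break
      inp <- inputs[[t]]
      if (!inp %in% sys$interface$directions[[cfg]]) {
        stop("input '", inp, "' at step ", t,
          " is not admissible for configuration '", cfg, "'", call. = FALSE)
      }
      u <- sys$update[[s]]
      s <- if (is.matrix(u)) sample_categorical(u[, inp]) else u[[inp]]
    }
    data.frame(step = 0:n, state = state, config = config,
      stringsAsFactors = FALSE)
  })
}
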