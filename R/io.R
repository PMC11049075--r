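# JSON/CSV serialization. Models and covers travel as strict-schema JSON
# (no extra fields); trajectories and consensus logs as CSV.

.model_fields <- c("states", "observations", "actions", "A", "B", "C", "D",
  "E", "gamma", "site_assignment", "admissibility")

model_to_list <- function(model, site_assignment = NULL, admissibility = NULL) {
  out <- list(states = model$states, observations = model$obs,
    actions = model$actions,
    A = unname(lapply(seq_len(nrow(model$A)), function(i) unname(model$A[i, ]))),
    B = lapply(model$B, function(m) {
      unname(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
    }),
    C = unname(model$C), D = unname(model$D), E = unname(model$E),
    gamma = model$gamma)
  if (!is.null(site_assignment)) out$site_assignment <- as.list(site_assignment)
  if (!is.null(admissibility)) out$admissibility <- admissibility
  out
}

#' Write a generative model to JSON
#'
#' Serializes the label sets, row-major probability tables, preference and
#' prior vectors, and precision to a strict-schema JSON document, optionally
#' with spatial annotations (`site_assignment`, `admissibility`).
#'
#' @param model A [generative_model()].
#' @param path Output file path.
#' @param site_assignment Optional named character vector state -> site.
#' @param admissibility Optional named list site -> admissible observations.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, site_assignment = NULL,
                        admissibility = NULL) {
  jsonlite::write_json(model_to_list(model, site_assignment, admissibility),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a generative model from JSON
#'
#' Strict inverse of [write_model()]: unknown fields are rejected, missing
#' required fields are named, and every probability table is re-validated
#' on load (a non-stochastic column is reported with its set and label).
#'
#' @param path JSON file path.
#' @return A list with `model` (a [generative_model()]) and, if present,
#'   `site_assignment` and `admissibility`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), .model_fields)
  if (length(unknown)) {
    stop("unknown field(s) in model file: ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }
  required <- c("states", "observations", "actions", "A", "B", "C", "D",
    "E", "gamma")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("missing field(s) in model file: ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  A <- stoch_map(matrix(unlist(doc$A), nrow = length(doc$observations),
    byrow = is.list(doc$A)), from = doc$states, to = doc$observations)
  B <- lapply(doc$B, function(tab) {
    stoch_map(matrix(unlist(tab), nrow = length(doc$states),
      byrow = is.list(tab)), from = doc$states, to = doc$states)
  })
  B <- B[doc$actions]
  model <- generative_model(A, B,
    C = categorical(doc$C, doc$observations, normalize = FALSE),
    D = categorical(doc$D, doc$states, normalize = FALSE),
    E = categorical(doc$E, doc$actions, normalize = FALSE),
    gamma = doc$gamma)
  out <- list(model = model)
  if (!is.null(doc$site_assignment)) {
    out$site_assignment <- unlist(doc$site_assignment)
  }
  if (!is.null(doc$admissibility)) {
    out$admissibility <- lapply(doc$admissibility, as.character)
  }
  out
}

#' Write and read polynomials as JSON
#'
#' Format: `{"positions": [...], "directions": {position: [...]}}`.
#'
#' @param p A `polynomial`.
#' @param path File path.
#' @return `path` (write) or a `polynomial` (read).
#' @export
write_polynomial <- function(p, path) {
  stopifnot(inherits(p, "polynomial"))
  jsonlite::write_json(list(positions = p$positions, directions = p$directions),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_polynomial
#' @export
read_polynomial <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  polynomial(doc$positions, as.list(doc$directions))
}

#' Write and read cover-plus-sections bundles as JSON
#'
#' Format: `{"base": [...], "patches": {agent: [...]}, "labels": [...],
#' "sections": {agent: {site: [probs]}}}`.
#'
#' @param cov A [cover()].
#' @param sections Named list of [section()]s.
#' @param path File path.
#' @return `path` (write) or a list with `cover` and `sections` (read).
#' @export
write_cover <- function(cov, sections, path) {
  stopifnot(inherits(cov, "cover"))
  sections <- check_sections(sections, cov)
  labels <- names(sections[[1]]$data[[1]])
  jsonlite::write_json(list(base = cov$base, patches = cov$patches,
    labels = labels,
    sections = lapply(sections, function(s) lapply(s$data, unname))),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cover
#' @export
read_cover <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- cover(doc$base, as.list(doc$patches))
  sections <- lapply(names(doc$sections), function(j) {
    section(j, lapply(doc$sections[[j]], function(v) {
      categorical(as.numeric(v), doc$labels, normalize = FALSE)
    }))
  })
  names(sections) <- names(doc$sections)
  list(cover = cov, sections = sections)
}

#' Flatten an ensemble trajectory to a data frame / CSV
#'
#' Columns: `step`, the true world `state`, and per agent its observation,
#' action, free energy, posterior belief per state, and expected free
#' energy per own action.
#'
#' @param traj An [simulate_ensemble()] trajectory.
#' @param path Optional CSV output path.
#' @return The data frame (invisibly if `path` is given).
#' @export
trajectory_frame <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  out <- data.frame(step = seq_len(traj$T), state = traj$states,
    stringsAsFactors = FALSE)
  for (j in seq_along(traj$ids)) {
    id <- traj$ids[j]
    out[[paste0("obs.", id)]] <- traj$obs[, j]
    out[[paste0("action.", id)]] <- traj$actions[, j]
    out[[paste0("F.", id)]] <- traj$F[, j]
    st <- names(traj$beliefs[[1]][[j]])
    for (s in st) {
      out[[paste0("belief.", id, ".", s)]] <-
        vapply(traj$beliefs, function(b) b[[j]][[s]], numeric(1))
    }
    acts <- names(traj$G[[1]][[j]])
    for (a in acts) {
      out[[paste0("G.", id, ".", a)]] <-
        vapply(traj$G, function(g) g[[j]][[a]], numeric(1))
    }
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a consensus run log to CSV
#'
#' Columns: `iteration`, `energy`, `max_discrepancy`.
#'
#' @param res Result of [run_consensus()].
#' @param path CSV output path.
#' @return The data frame, invisibly.
#' @export
write_consensus_log <- function(res, path) {
  out <- data.frame(iteration = seq_along(res$trace) - 1L,
    energy = res$trace, max_discrepancy = res$discrepancy)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
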