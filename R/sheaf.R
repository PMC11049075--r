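#' Finite cover of a shared base space
#'
#' The substrate for gluing world models: a finite set of sites, one patch
#' (subset of sites) per agent, and all pairwise overlaps precomputed.
#' Patches must be non-empty and their union must cover the base.
#'
#' @param base Character vector of site labels.
#' @param patches Named list (agent id -> character vector of sites).
#' @return An object of class `"cover"` with an `overlaps` field listing
#'   every pair with a non-empty intersection.
#' @export
cover <- function(base, patches) {
  assert_labels(base, "base sites")
  stopifnot(is.list(patches), !is.null(names(patches)))
  for (j in names(patches)) {
    assert_labels(patches[[j]], paste0("patch '", j, "'"))
    if (!all(patches[[j]] %in% base)) {
      stop("patch '", j, "' leaves the base space", call. = FALSE)
    }
  }
  if (!setequal(unique(unlist(patches)), base)) {
    stop("union of patches must cover the base", call. = FALSE)
  }
  ids <- names(patches)
  overlaps <- list()
  if (length(ids) > 1L) {
    for (a in seq_len(length(ids) - 1L)) {
      for (b in (a + 1L):length(ids)) {
        shared <- intersect(patches[[a]], patches[[b]])
        if (length(shared)) {
          overlaps[[paste(ids[a], ids[b], sep = "~")]] <-
            list(pair = c(ids[a], ids[b]), sites = shared)
        }
      }
    }
  }
  structure(list(base = base, patches = patches, overlaps = overlaps),
    class = "cover")
}

#' @export
print.cover <- function(x, ...) {
  cat("<cover> ", length(x$base), " sites, ", length(x$patches),
    " patches, ", length(x$overlaps), " overlapping pair(s)\n", sep = "")
  invisible(x)
}

#' Local section of the sheaf of world models
#'
#' One agent's local data: a categorical vector per site of its patch
#' (beliefs, preferences, or parameter rows indexed by the shared space).
#'
#' @param agent Agent id.
#' @param data Named list (site -> categorical vector); sites define the
#'   patch the section lives on.
#' @return An object of class `"section"`.
#' @export
section <- function(agent, data) {
  stopifnot(is.list(data), !is.null(names(data)))
  assert_labels(names(data), "section sites")
  for (site in names(data)) {
    validate_categorical(data[[site]], paste0("section at site '", site, "'"))
  }
  structure(list(agent = agent, data = data), class = "section")
}

#' Restrict a section to a subset of its sites
#'
#' The restriction maps of the sheaf are sub-indexing (identity on shared
#' sites), so restriction is functorial: restricting twice equals
#' restricting once to the smaller subset.
#'
#' @param s A [section()].
#' @param sites Character vector of sites, a subset of the section's patch.
#' @return A [section()] on `sites`.
#' @export
restrict_section <- function(s, sites) {
  stopifnot(inherits(s, "section"))
  missing <- setdiff(sites, names(s$data))
  if (length(missing)) {
    stop("site(s) outside the section's patch: ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  section(s$agent, s$data[sites])
}

# Sections as a named list keyed by agent id, aligned with a cover.
check_sections <- function(sections, cov) {
  stopifnot(inherits(cov, "cover"))
  ids <- names(cov$patches)
  if (is.null(names(sections))) {
    names(sections) <- vapply(sections, `[[`, character(1), "agent")
  }
  if (!setequal(names(sections), ids)) {
    stop("need exactly one section per agent of the cover", call. = FALSE)
  }
  for (j in ids) {
    if (!setequal(names(sections[[j]]$data), cov$patches[[j]])) {
      stop("section of '", j, "' does not match its patch", call. = FALSE)
    }
  }
  sections[ids]
}

#' Disagreement obstruction between sections
#'
#' Quantifies the failure of the gluing condition: for every overlapping
#' pair of patches and every shared site, the squared Euclidean distance
#' between the two site-vectors, plus the total-variation discrepancy used
#' by [check_gluing()]. The total energy is zero exactly when all sections
#' agree on all overlaps; disjoint covers are flagged vacuously glueable.
#'
#' @param sections Named list of [section()]s, one per agent of the cover.
#' @param cov A [cover()].
#' @return An object of class `"obstruction_report"`: `energy`,
#'   `max_discrepancy` (max total-variation distance over pairs and sites),
#'   per-pair breakdown `pairs`, and logical `vacuous`.
#' @export
disagreement <- function(sections, cov) {
  sections <- check_sections(sections, cov)
  rows <- list()
  energy <- 0
  max_disc <- 0
  for (ov in cov$overlaps) {
    j <- ov$pair[1]; k <- ov$pair[2]
    for (site in ov$sites) {
      vj <- sections[[j]]$data[[site]]
      vk <- sections[[k]]$data[[site]]
      check_same_support(vj, vk)
      sq <- sum((vj - vk)^2)
      tv <- 0.5 * sum(abs(vj - vk))
      energy <- energy + sq
      max_disc <- max(max_disc, tv)
      rows[[length(rows) + 1L]] <- data.frame(agent_a = j, agent_b = k,
        site = site, sq_dist = sq, tv_dist = tv, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(agent_a = character(), agent_b = character(), site = character(),
      sq_dist = numeric(), tv_dist = numeric(), stringsAsFactors = FALSE)
  structure(list(energy = energy, max_discrepancy = max_disc, pairs = pairs,
    vacuous = length(cov$overlaps) == 0L),
    class = "obstruction_report")
}

#' @export
print.obstruction_report <- function(x, ...) {
  cat(sprintf("<obstruction> energy = %.6g, max TV discrepancy = %.6g%s\n",
    x$energy, x$max_discrepancy,
    if (x$vacuous) " (no overlaps: vacuously glueable)" else ""))
  invisible(x)
}

#' Can the sections be glued?
#'
#' True when the maximum total-variation discrepancy on overlaps is within
#' `tol`; the obstruction report is attached either way.
#'
#' @inheritParams disagreement
#' @param tol Non-negative tolerance on the per-site discrepancy.
#' @return List with logical `ok` and `report`.
#' @export
check_gluing <- function(sections, cov, tol = 1e-9) {
  rep <- disagreement(sections, cov)
  list(ok = rep$max_discrepancy <= tol, report = rep)
}

#' Glue consistent sections into a global section
#'
#' Assigns to every base site the (renormalized) average of all sections
#' covering it; by the gluing precondition these agree within `tol`, and
#' restricting the result to any patch reproduces the corresponding local
#' section to the same order.
#'
#' @inheritParams check_gluing
#' @return A named list (site -> categorical vector) over the whole base,
#'   of class `"global_section"`.
#' @export
glue_sections <- function(sections, cov, tol = 1e-9) {
  chk <- check_gluing(sections, cov, tol)
  if (!chk$ok) {
    stop("sections do not glue: max discrepancy ",
      format(chk$report$max_discrepancy), " exceeds tol ", format(tol),
      call. = FALSE)
  }
  sections <- check_sections(sections, cov)
  out <- list()
  for (site in cov$base) {
    owners <- names(cov$patches)[vapply(cov$patches, function(p) site %in% p, logical(1))]
    vecs <- lapply(owners, function(j) sections[[j]]$data[[site]])
    avg <- Reduce(`+`, vecs) / length(vecs)
    out[[site]] <- categorical(avg, names(vecs[[1]]))
  }
  structure(out, class = "global_section")
}

#' One synchronous consensus step
#'
#' Mean diffusion on the cover: at every site, each owning agent moves its
#' vector a fraction `eta` toward the mean of all owners' vectors at that
#' site, then renormalizes (a guard against floating-point drift only, since
#' a convex combination of normalized vectors is normalized). Sites with a
#' single owner are unchanged; consistent sections are a fixed point.
#'
#' @inheritParams disagreement
#' @param eta Step size in (0, 1].
#' @return The updated named list of sections.
#' @export
consensus_step <- function(sections, cov, eta = 0.5) {
  if (!is.numeric(eta) || eta <= 0 || eta > 1) {
    stop("eta must lie in (0, 1]", call. = FALSE)
  }
  sections <- check_sections(sections, cov)
  for (site in cov$base) {
    owners <- names(cov$patches)[vapply(cov$patches, function(p) site %in% p, logical(1))]
    if (length(owners) < 2L) next
    vecs <- lapply(owners, function(j) sections[[j]]$data[[site]])
    m <- Reduce(`+`, vecs) / length(vecs)
    for (j in owners) {
      v <- sections[[j]]$data[[site]]
      sections[[j]]$data[[site]] <- categorical((1 - eta) * v + eta * m, names(v))
    }
  }
  sections
}

#' Iterate consensus dynamics until the sections (nearly) glue
#'
#' Runs [consensus_step()] until the disagreement energy falls to `tol` or
#' `max_iter` is reached, recording the energy trace (which is
#' non-increasing for `eta` in (0, 1]). Under a connected overlap structure
#' the dynamics converge to the per-site mean of the initial vectors.
#'
#' @inheritParams consensus_step
#' @param max_iter Iteration cap.
#' @param tol Energy threshold for convergence.
#' @return List with `sections`, numeric `trace` (energy per recorded
#'   iteration, starting with the initial energy), and logical `converged`.
#' @export
run_consensus <- function(sections, cov, eta = 0.5, max_iter = 100, tol = 1e-9) {
  sections <- check_sections(sections, cov)
  rep0 <- disagreement(sections, cov)
  trace <- rep0$energy
  discrepancy <- rep0$max_discrepancy
  i <- 0L
  while (trace[length(trace)] > tol && i < max_iter) {
    sections <- consensus_step(sections, cov, eta)
    rep_i <- disagreement(sections, cov)
    trace <- c(trace, rep_i$energy)
    discrepancy <- c(discrepancy, rep_i$max_discrepancy)
    i <- i + 1L
  }
  list(sections = sections, trace = trace, discrepancy = discrepancy,
    converged = trace[length(trace)] <= tol)
}

#' Validate the spatial structure of a generative model
#'
#' A spatial generative model must respect the geometry of the shared
#' space: observations may only be predicted where they may be made. Given
#' an assignment of hidden states to sites and the set of admissible
#' observations per site, checks that the likelihood places zero mass on
#' every inadmissible (state, observation) pair.
#'
#' @param model A [generative_model()].
#' @param site_assignment Named character vector: state -> site.
#' @param admissibility Named list: site -> character vector of admissible
#'   observation labels.
#' @return An object of class `"spatial_model_check"` with logical `ok` and
#'   a data frame `violations` (state, site, observation, mass).
#' @export
validate_spatial_model <- function(model, site_assignment, admissibility) {
  stopifnot(inherits(model, "generative_model"))
  if (!setequal(names(site_assignment), model$states)) {
    stop("every state must be assigned a site", call. = FALSE)
  }
  rows <- list()
  for (s in model$states) {
    site <- site_assignment[[s]]
    allowed <- admissibility[[site]]
    if (is.null(allowed)) {
      stop("no admissible observations declared for site '", site, "'",
        call. = FALSE)
    }
    bad <- setdiff(model$obs, allowed)
    for (o in bad) {
      if (model$A[o, s] > 0) {
        rows[[length(rows) + 1L]] <- data.frame(state = s, site = site,
          observation = o, mass = model$A[o, s], stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(state = character(), site = character(),
      observation = character(), mass = numeric(), stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
    class = "spatial_model_check")
}

#' @export
print.spatial_model_check <- function(x, ...) {
  if (x$ok) cat("<spatial_model_check> pass\n") else {
    cat("<spatial_model_check> FAIL:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}
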