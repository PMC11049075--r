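#' Finite polynomial functors
#'
#' A finite polynomial `p = sum_i y^(p[i])` is stored as a labelled set of
#' *positions* (the configurations an interface can adopt, e.g. actions) and,
#' for each position, a labelled set of *directions* (the sense data
#' admissible in that configuration). Polynomials model agent interfaces:
#' the monomial `A y^S` recovers the classical Markov blanket with actions
#' `A` and sense data `S`.
#'
#' @param positions Character vector of position labels.
#' @param directions Named list (one entry per position) of character vectors
#'   of direction labels. A single unnamed character vector is recycled to
#'   every position (monomial shorthand).
#' @return An object of class `"polynomial"`.
#' @examples
#' polynomial(c("i1", "i2"), list(i1 = c("d1", "d2"), i2 = "d1"))
#' @export
polynomial <- function(positions, directions) {
  assert_labels(positions, "positions")
  if (is.character(directions)) {
    directions <- stats::setNames(rep(list(directions), length(positions)), positions)
  }
  if (!is.list(directions) || !identical(sort(names(directions)), sort(positions))) {
    stop("directions must be a named list with one entry per position", call. = FALSE)
  }
  directions <- directions[positions]
  for (i in positions) assert_labels(directions[[i]], paste0("directions of '", i, "'"))
  structure(list(positions = positions, directions = directions),
    class = "polynomial")
}

#' @export
print.polynomial <- function(x, ...) {
  sizes <- direction_sizes(x)
  cat("<polynomial> ", length(x$positions), " position(s): ",
    paste0(x$positions, ":y^", sizes, collapse = " + "), "\n", sep = "")
  invisible(x)
}

direction_sizes <- function(p) vapply(p$directions, length, integer(1))

#' Monomial interface (classical Markov blanket)
#'
#' Builds `A y^S`: every configuration in `configs` carries the same direction
#' set `senses`, so the total set has cardinality `|A| * |S|`.
#'
#' @param configs Character labels of configurations/actions.
#' @param senses Character labels of sense data.
#' @return A `polynomial`.
#' @export
make_monomial <- function(configs, senses) {
  polynomial(configs, senses)
}

#' Total set of a polynomial
#'
#' The disjoint union of all direction sets: labels are
#' `"position/direction"` pairs, so the cardinality is `sum_i |p[i]|`.
#'
#' @param p A `polynomial`.
#' @return Character vector of pair labels.
#' @export
total_set <- function(p) {
  stopifnot(inherits(p, "polynomial"))
  unlist(lapply(p$positions, function(i) {
    paste(i, p$directions[[i]], sep = "/")
  }), use.names = FALSE)
}

#' Trivial interface y
#'
#' One position, one direction: the closed interface.
#' @return A `polynomial`.
#' @export
poly_y <- function() polynomial("*", list(`*` = "*"))

#' Tensor (parallel product) of polynomials
#'
#' Places two interfaces side by side: positions are pairs of positions,
#' directions are pairs of directions, so
#' `|(p (x) q)(1)| = |p(1)| * |q(1)|` and the direction set at `(i, i')` has
#' `|p[i]| * |q[i']|` elements. Pair labels are joined with `"|"`.
#'
#' @param p,q Polynomials.
#' @return A `polynomial`.
#' @export
poly_tensor <- function(p, q) {
  stopifnot(inherits(p, "polynomial"), inherits(q, "polynomial"))
  pos <- as.vector(t(outer(p$positions, q$positions, paste, sep = "|")))
  dirs <- list()
  for (i in p$positions) {
    for (j in q$positions) {
      dirs[[paste(i, j, sep = "|")]] <-
        as.vector(t(outer(p$directions[[i]], q$directions[[j]], paste, sep = "|")))
    }
  }
  polynomial(pos, dirs)
}

# ---- morphisms ---------------------------------------------------------

#' Construct a polynomial morphism
#'
#' A morphism `p -> q` is a forward map on positions together with, for each
#' source position `i`, a backward map `q[forward(i)] -> p[i]` on directions
#' (deterministic: named character; stochastic feedback: a column-stochastic
#' matrix built by [stoch_map()]).
#'
#' @param source,target Polynomials.
#' @param forward Named character vector: source position -> target position.
#' @param backward Named list over source positions; each element maps the
#'   target directions at `forward[i]` to source directions at `i`.
#' @return An object of class `"poly_morphism"`.
#' @export
poly_morphism <- function(source, target, forward, backward) {
  stopifnot(inherits(source, "polynomial"), inherits(target, "polynomial"))
  if (!identical(sort(names(forward)), sort(source$positions))) {
    stop("forward must be total on source positions", call. = FALSE)
  }
  if (!all(forward %in% target$positions)) {
    stop("forward maps outside target positions", call. = FALSE)
  }
  for (i in source$positions) {
    bk <- backward[[i]]
    dom <- target$directions[[forward[[i]]]]
    cod <- source$directions[[i]]
    if (is.matrix(bk)) {
      validate_stoch_map(bk)
      ok <- identical(colnames(bk), dom) && identical(rownames(bk), cod)
    } else {
      ok <- identical(sort(names(bk)), sort(dom)) && all(bk %in% cod)
    }
    if (!ok) {
      stop("backward map at position '", i, "' is not total ",
        "q[forward(i)] -> p[i]", call. = FALSE)
    }
  }
  structure(list(source = source, target = target,
    forward = forward[source$positions], backward = backward[source$positions]),
    class = "poly_morphism")
}

#' Identity morphism on a polynomial
#' @param p A `polynomial`.
#' @return A `poly_morphism`.
#' @export
poly_identity <- function(p) {
  fwd <- stats::setNames(p$positions, p$positions)
  bk <- lapply(p$directions, function(d) stats::setNames(d, d))
  poly_morphism(p, p, fwd, bk)
}

#' Compose polynomial morphisms
#'
#' For `f : p -> q` and `g : q -> r`, the composite has forward
#' `g1 o f1` and backward maps `f_sharp o g_sharp` (directions flow
#' backwards).
#'
#' @param g,f Morphisms with `f$target` equal to `g$source`.
#' @return A `poly_morphism` from `f$source` to `g$target`.
#' @export
compose_poly_morphism <- function(g, f) {
  if (!identical(f$target$positions, g$source$positions)) {
    stop("cannot compose: target of f must equal source of g", call. = FALSE)
  }
  fwd <- stats::setNames(g$forward[f$forward], names(f$forward))
  bk <- lapply(names(f$forward), function(i) {
    gi <- g$backward[[f$forward[[i]]]] # r[g1 f1 i] -> q[f1 i]
    fi <- f$backward[[i]]              # q[f1 i]    -> p[i]
    stats::setNames(fi[gi], names(gi))
  })
  names(bk) <- names(f$forward)
  poly_morphism(f$source, g$target, fwd, bk)
}

# Predicted number of morphisms p -> q, plus the forward-map count.
.morphism_count <- function(p, q) {
  np <- length(p$positions)
  nq <- length(q$positions)
  n_fwd <- nq^np
  sp <- direction_sizes(p)
  sq <- direction_sizes(q)
  fwd_grid <- expand.grid(rep(list(seq_len(nq)), np), KEEP.OUT.ATTRS = FALSE)
  per_fwd <- apply(as.matrix(fwd_grid), 1L, function(tg) {
    prod(sp^sq[tg])
  })
  list(n_fwd = n_fwd, total = sum(per_fwd))
}

#' Enumerate all morphisms between two polynomials
#'
#' Exhaustive, duplicate-free enumeration of every (forward, backward) pair.
#' The predicted count is computed first and the enumeration refuses to run
#' if it exceeds `cap` (no silent sampling). Morphisms are compared
#' on-the-nose (by labels), not up to relabelling.
#'
#' @param p,q Polynomials.
#' @param cap Maximum number of morphisms to materialize.
#' @return List of `poly_morphism` objects.
#' @export
enumerate_morphisms <- function(p, q, cap = 1e5) {
  stopifnot(inherits(p, "polynomial"), inherits(q, "polynomial"))
  nq <- length(q$positions)
  np <- length(p$positions)
  if (nq^np > cap) {
    stop("predicted forward-map count ", nq^np, " exceeds cap ", cap, call. = FALSE)
  }
  cnt <- .morphism_count(p, q)
  if (cnt$total > cap) {
    stop("predicted morphism count ", cnt$total, " exceeds cap ", cap, call. = FALSE)
  }
  out <- list()
  fwd_grid <- expand.grid(rep(list(q$positions), np),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(fwd_grid))) {
    fwd <- stats::setNames(as.character(fwd_grid[r, ]), p$positions)
    # all backward families: per source position, all functions
    # q[fwd(i)] -> p[i]
    per_pos <- lapply(p$positions, function(i) {
      dom <- q$directions[[fwd[[i]]]]
      cod <- p$directions[[i]]
      g <- expand.grid(rep(list(cod), length(dom)),
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(k) {
        stats::setNames(as.character(g[k, ]), dom)
      })
    })
    combos <- expand.grid(lapply(per_pos, seq_along), KEEP.OUT.ATTRS = FALSE)
    for (k in seq_len(nrow(combos))) {
      bk <- lapply(seq_len(np), function(ii) per_pos[[ii]][[combos[k, ii]]])
      names(bk) <- p$positions
      out[[length(out) + 1L]] <- poly_morphism(p, q, fwd, bk)
    }
  }
  out
}

#' Hom polynomial [p, q]
#'
#' The internal hom: positions are the morphisms `p -> q` (patterns of
#' interaction), and the direction set at a morphism `phi` is the disjoint
#' union over source positions `i` of `q[phi1(i)]`. Constructed eagerly via
#' [enumerate_morphisms()]; refuses above `cap`.
#'
#' @param p,q Polynomials.
#' @param cap Enumeration cap.
#' @return A `polynomial` whose positions carry the underlying morphisms in
#'   attribute `"morphisms"`.
#' @export
poly_hom <- function(p, q, cap = 1e5) {
  ms <- enumerate_morphisms(p, q, cap = cap)
  pos <- sprintf("m%03d", seq_along(ms))
  dirs <- lapply(ms, function(phi) {
    unlist(lapply(p$positions, function(i) {
      paste(i, q$directions[[phi$forward[[i]]]], sep = "/")
    }), use.names = FALSE)
  })
  names(dirs) <- pos
  out <- polynomial(pos, dirs)
  attr(out, "morphisms") <- stats::setNames(ms, pos)
  out
}

# ---- cardinality profiles ---------------------------------------------

# A profile is the testable shadow of a polynomial: its position count and
# the multiset of direction-set sizes, stored aggregated as a named count
# vector (names = sizes). Two finite polynomials are isomorphic iff their
# profiles agree, which is what curry_check() certifies.
.aggregate_profile <- function(sizes, counts) {
  agg <- tapply(counts, sizes, sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Cardinality profile of a polynomial
#'
#' @param p A `polynomial`.
#' @return List with `positions` (count) and `profile` (named numeric vector:
#'   direction-set size -> number of positions with that size).
#' @export
poly_profile <- function(p) {
  sizes <- direction_sizes(p)
  list(positions = length(p$positions),
    profile = .aggregate_profile(sizes, rep(1, length(sizes))))
}

# Profile of [p, q] computed combinatorially, given p's per-position
# direction sizes and q's (aggregated) profile. All morphisms sharing a
# forward map have the same direction size sum_i |q[phi1(i)]|, and their
# number is prod_i |p[i]|^|q[phi1(i)]|; forward maps are aggregated by the
# size class of each target position.
.hom_profile_sizes <- function(p_sizes, q_profile, cap = 1e7) {
  q_sizes <- as.numeric(names(q_profile))
  q_mult <- as.numeric(q_profile)
  n <- length(p_sizes)
  k <- length(q_sizes)
  if (k^n > cap) stop("size-class assignment count exceeds cap", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n), KEEP.OUT.ATTRS = FALSE))
  dir_size <- numeric(nrow(grid))
  count <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cls <- grid[r, ]
    dir_size[r] <- sum(q_sizes[cls])
    count[r] <- prod(q_mult[cls]) * prod(p_sizes^q_sizes[cls])
  }
  prof <- .aggregate_profile(dir_size, count)
  list(positions = sum(count), profile = prof)
}

#' Check the currying isomorphism [p, [q, r]] = [p (x) q, r]
#'
#' Computes the cardinality profile (position count plus direction-size
#' multiset) of both sides combinatorially and reports whether they agree.
#' Profile equality is the finite, testable shadow of the natural
#' isomorphism between the two hom polynomials.
#'
#' @param p,q,r Polynomials.
#' @param cap Guard on the internal combinatorial enumeration.
#' @return List of class `"curry_report"` with `left`, `right` (profiles)
#'   and logical `isomorphic`.
#' @export
curry_check <- function(p, q, r, cap = 1e7) {
  inner <- .hom_profile_sizes(direction_sizes(q), poly_profile(r)$profile, cap)
  left <- .hom_profile_sizes(direction_sizes(p), inner$profile, cap)
  pq <- as.vector(outer(direction_sizes(p), direction_sizes(q)))
  right <- .hom_profile_sizes(pq, poly_profile(r)$profile, cap)
  iso <- isTRUE(all.equal(left$positions, right$positions)) &&
    identical(names(left$profile), names(right$profile)) &&
    isTRUE(all.equal(unname(left$profile), unname(right$profile)))
  structure(list(left = left, right = right, isomorphic = iso),
    class = "curry_report")
}

#' @export
print.curry_report <- function(x, ...) {
  cat("<curry_report> [p,[q,r]] vs [p(x)q,r]\n")
  cat("  positions:", x$left$positions, "vs", x$right$positions, "\n")
  cat("  isomorphic:", x$isomorphic, "\n")
  invisible(x)
}
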