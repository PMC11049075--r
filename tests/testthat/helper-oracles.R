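# Shared helpers and independent oracles. The oracles recompute quantities
# by direct summation / brute force, independently of the package's code
# paths.

rand_cat <- function(labels) {
  w <- -log(runif(length(labels)))
  stats::setNames(w / sum(w), labels)
}

rand_map <- function(from, to) {
  m <- vapply(from, function(x) unname(rand_cat(to)), numeric(length(to)))
  dimnames(m) <- list(to, from)
  m
}

# Eq-by-eq free energy by direct summation: E_q[ln q - ln A(o|.) - ln prior].
fe_direct <- function(model, q, prior, o) {
  tot <- 0
  for (s in model$states) {
    if (q[[s]] <= 0) next
    tot <- tot + q[[s]] *
      (log(q[[s]]) - log(max(model$A[o, s], 1e-16)) - log(max(prior[[s]], 1e-16)))
  }
  tot
}

# Expected free energy by direct double loop over (state, observation)
# outcomes, in the single-expectation form
# G = E_{Q(o,s)}[ln Q(s) - ln Q(s|o) - ln C(o)] with Q(o,s) = A(o|s) q(s).
efe_direct <- function(model, q_next) {
  q_obs <- stats::setNames(numeric(length(model$obs)), model$obs)
  for (o in model$obs) {
    q_obs[[o]] <- sum(model$A[o, ] * q_next)
  }
  G <- 0
  for (s in model$states) {
    for (o in model$obs) {
      w <- model$A[o, s] * q_next[[s]]
      if (w <= 0) next
      post_so <- w / q_obs[[o]] # Q(s | o)
      G <- G + w * (log(max(q_next[[s]], 1e-16)) - log(post_so) -
        log(max(model$C[[o]], 1e-16)))
    }
  }
  G
}

# All direction-size shapes (positions x per-position sizes) up to the given
# bounds, realized as concrete labelled polynomials.
poly_shape_grid <- function(max_pos = 2, max_dir = 2) {
  out <- list()
  for (np in seq_len(max_pos)) {
    sizes <- expand.grid(rep(list(seq_len(max_dir)), np))
    for (r in seq_len(nrow(sizes))) {
      pos <- paste0("p", seq_len(np))
      dirs <- lapply(seq_len(np), function(i) paste0("d", seq_len(sizes[r, i])))
      names(dirs) <- pos
      out[[length(out) + 1L]] <- polynomial(pos, dirs)
    }
  }
  out
}

# Morphism equality on the nose.
same_morphism <- function(a, b) {
  identical(a$forward, b$forward) && identical(a$backward, b$backward)
}
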