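#' Finite categorical probability primitives
#'
#' Beliefs, priors and policies are represented as *categorical* vectors:
#' named numeric vectors of non-negative probabilities summing to one, whose
#' names are the labels of a finite support. Label order is the single source
#' of truth for alignment: operations require identical label sequences and
#' never align by position across differently labelled sets.
#'
#' @param probs Numeric vector of non-negative weights.
#' @param labels Character labels, one per entry; defaults to `names(probs)`.
#' @param normalize Divide by the total mass? If `FALSE`, the input must
#'   already sum to one within `1e-9`.
#' @return A named numeric probability vector.
#' @examples
#' categorical(c(left = 1, right = 3))
#' @export
categorical <- function(probs, labels = names(probs), normalize = TRUE) {
  assert_labels(labels, "support labels")
  if (length(probs) != length(labels)) {
    stop("probs and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  total <- sum(probs)
  if (normalize) {
    if (total <= 0) stop("total mass must be positive", call. = FALSE)
    probs <- probs / total
  } else if (abs(total - 1) > 1e-9) {
    stop("probabilities must sum to 1 within 1e-9", call. = FALSE)
  }
  stats::setNames(as.numeric(probs), labels)
}

validate_categorical <- function(x, what = "categorical") {
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop(what, " must have unique labels", call. = FALSE)
  }
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-9) {
    stop(what, " must be a probability vector summing to 1", call. = FALSE)
  }
  invisible(x)
}

check_same_support <- function(q, p) {
  if (is.null(names(q)) || is.null(names(p)) || !identical(names(q), names(p))) {
    stop("supports differ: labels must match exactly, in order", call. = FALSE)
  }
}

#' Softmax over labelled scores
#'
#' Computes `sigma(-gamma * values)`: the categorical distribution obtained by
#' exponentiating negated, precision-scaled scores and normalizing. Used for
#' action selection, where `values` are expected free energies and `gamma` is
#' the precision controlling the stochasticity of choice; `gamma = 0` yields
#' the uniform distribution. Invariant to adding a constant to all values.
#'
#' @param values Named (or unnamed) finite numeric scores, one per option.
#' @param gamma Non-negative precision.
#' @return A categorical vector over the option labels.
#' @examples
#' softmax_policy(c(a = 0, b = log(2)), gamma = 1) # c(2/3, 1/3)
#' @export
softmax_policy <- function(values, gamma = 1) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  z <- -gamma * values
  z <- z - max(z) # shift invariance, numerical stability
  w <- exp(z)
  p <- w / sum(w)
  if (is.null(names(values))) names(p) <- paste0("v", seq_along(values))
  p
}

#' Kullback-Leibler divergence between categorical vectors
#'
#' `sum(q * log(q / p))` with the `0 * log(0) = 0` convention. Returns `+Inf`
#' when `q` places mass where `p` has none (absolute-continuity failure); this
#' function is a diagnostic and deliberately does not clamp.
#'
#' @param q,p Categorical vectors over the same labelled support.
#' @return Non-negative real, possibly `Inf`; zero iff `q == p`.
#' @examples
#' kl_divergence(c(a = 1, b = 0), c(a = 0.5, b = 0.5)) # log(2)
#' @export
kl_divergence <- function(q, p) {
  check_same_support(q, p)
  pos <- q > 0
  if (any(p[pos] == 0)) return(Inf)
  sum(q[pos] * (log(q[pos]) - log(p[pos])))
}

# Shannon entropy with clamped logs (objective-side convention).
entropy_categorical <- function(p) {
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Conditional probability tables as stochastic maps
#'
#' A stochastic map `X ~> Y` is stored as a `|Y| x |X|` matrix whose columns
#' are categorical vectors over the target labels (rownames) given each source
#' label (colnames).
#'
#' @param table Numeric matrix, targets in rows, sources in columns.
#' @param from,to Optional character labels overriding `colnames`/`rownames`.
#' @return A validated column-stochastic matrix with dimnames.
#' @examples
#' stoch_map(matrix(c(0.9, 0.1, 0.2, 0.8), 2), from = c("x1", "x2"), to = c("y1", "y2"))
#' @export
stoch_map <- function(table, from = colnames(table), to = rownames(table)) {
  table <- as.matrix(table)
  assert_labels(to, "target labels")
  assert_labels(from, "source labels")
  if (nrow(table) != length(to) || ncol(table) != length(from)) {
    stop("table dimensions do not match label sets", call. = FALSE)
  }
  dimnames(table) <- list(to, from)
  validate_stoch_map(table)
  table
}

validate_stoch_map <- function(m, what = "stochastic map") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must carry target rownames and source colnames", call. = FALSE)
  }
  if (any(m < -1e-12)) stop(what, " has negative entries", call. = FALSE)
  bad <- which(abs(colSums(m) - 1) > 1e-9)
  if (length(bad)) {
    stop(what, ": column '", colnames(m)[bad[1]], "' sums to ",
      format(colSums(m)[bad[1]]), ", not 1", call. = FALSE)
  }
  invisible(m)
}

#' Compose stochastic maps
#'
#' Chapman-Kolmogorov composition: `(g o f)(z | x) = sum_y g(z | y) f(y | x)`,
#' realized as the matrix product `g %*% f`. Requires `f`'s target labels to
#' equal `g`'s source labels exactly.
#'
#' @param g Stochastic map `Y ~> Z`.
#' @param f Stochastic map `X ~> Y`.
#' @return The composite stochastic map `X ~> Z`.
#' @export
compose_stochastic <- function(g, f) {
  validate_stoch_map(g); validate_stoch_map(f)
  if (!identical(colnames(g), rownames(f))) {
    stop("cannot compose: target of f must equal source of g", call. = FALSE)
  }
  out <- g %*% f
  out / rep(colSums(out), each = nrow(out)) # renormalize float drift only
}

identity_stoch_map <- function(labels) {
  assert_labels(labels)
  stoch_map(diag(length(labels)), from = labels, to = labels)
}
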