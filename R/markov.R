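#' Specify a stationary first-order Markov chain fixture
#'
#' The chain is the statistical test bed of the package: its entropy rate,
#' transition rows, and mean first-passage commute times are available in
#' closed form, so every stochastic claim about the sequence model can be
#' checked against an exact reference.
#'
#' @param transition_matrix square row-stochastic matrix (rows sum to 1
#'   within 1e-8, entries non-negative); must be irreducible.
#' @param length number of symbols to sample.
#' @param seed optional integer seed used by [sample_chain()].
#' @return An object of class `markov_chain_spec`.
#' @export
markov_chain_spec <- function(transition_matrix, length, seed = NULL) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) abort("`transition_matrix` must be square.")
  if (any(P < 0)) abort("transition probabilities must be non-negative.")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    abort("every row of `transition_matrix` must sum to 1.")
  if (!is_irreducible(P))
    abort("`transition_matrix` is reducible; fixture chains must be irreducible.")
  structure(list(n_states = nrow(P), transition_matrix = P,
                 length = as.integer(length), seed = seed),
            class = "markov_chain_spec")
}

# reachability check by boolean matrix closure
is_irreducible <- function(P) {
  A <- P > 0
  R <- A | diag(TRUE, nrow(A))
  for (i in seq_len(ceiling(log2(nrow(A))) + 1)) R <- (R %*% R) > 0
  all(R)
}

#' Stationary distribution of a transition matrix
#'
#' Leading left eigenvector of `P`, renormalized to sum to 1.
#'
#' @param P row-stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

#' Sample a label series from a Markov chain fixture
#'
#' The initial state is drawn from the stationary distribution; subsequent
#' states follow the transition matrix. Deterministic given the spec's seed.
#'
#' @param spec a [markov_chain_spec()].
#' @return Integer label vector (0-based) of length `spec$length`.
#' @export
sample_chain <- function(spec) {
  stopifnot(inherits(spec, "markov_chain_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  P <- spec$transition_matrix
  n <- spec$length
  cum <- t(apply(P, 1, cumsum))
  pi0 <- stationary_distribution(P)
  out <- integer(n)
  u <- runif(n)
  cur <- findInterval(u[1], cumsum(pi0)) + 1L
  out[1] <- cur
  for (t in seq_len(n - 1L)) {
    cur <- findInterval(u[t + 1L], cum[cur, ]) + 1L
    out[t + 1L] <- cur
  }
  out - 1L
}

#' Entropy rate of a stationary Markov chain
#'
#' \eqn{h = -\sum_i \pi_i \sum_j P_{ij} \ln P_{ij}} in nats per symbol, with
#' the convention \eqn{0 \ln 0 = 0}. This is the floor of the achievable
#' per-symbol cross-entropy of any sequence model of the chain.
#'
#' @param P row-stochastic matrix (or a `markov_chain_spec`).
#' @return Entropy rate in nats/symbol.
#' @export
entropy_rate <- function(P) {
  if (inherits(P, "markov_chain_spec")) P <- P$transition_matrix
  pi0 <- stationary_distribution(P)
  lp <- ifelse(P > 0, log(P), 0)
  -sum(pi0 * rowSums(P * lp))
}

#' Maximum-likelihood transition-matrix estimate
#'
#' Row-normalized transition counts of a label series. Rows for unvisited
#' states are `NA` (with a warning).
#'
#' @param labels integer label series (0-based).
#' @param n_states number of states.
#' @return Row-stochastic matrix estimate.
#' @export
ml_transition_estimate <- function(labels, n_states) {
  labels <- as.integer(labels)
  counts <- matrix(0, n_states, n_states)
  from <- labels[-length(labels)] + 1L
  to <- labels[-1] + 1L
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  rs <- rowSums(counts)
  if (any(rs == 0)) warn("unvisited state(s): NA row(s) in the estimate.")
  sweep(counts, 1, ifelse(rs > 0, rs, NA_real_), "/")
}

#' Mean first-passage and commute times of a Markov chain
#'
#' Mean first-passage times \eqn{m_{ij}} solve the standard linear system
#' \eqn{(I - P_{-j,-j})\, m_{\cdot j} = 1}; the commute time is the
#' symmetric round trip \eqn{m_{ij} + m_{ji}}.
#'
#' @param P row-stochastic matrix (or a `markov_chain_spec`).
#' @return A list with `mfpt` (matrix, `mfpt[i, j]` = expected steps from i
#'   to first arrival at j; 0 on the diagonal) and `commute` (symmetric
#'   matrix of round-trip times).
#' @export
mfpt_commute <- function(P) {
  if (inherits(P, "markov_chain_spec")) P <- P$transition_matrix
  n <- nrow(P)
  mfpt <- matrix(0, n, n)
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    A <- diag(length(keep)) - P[keep, keep, drop = FALSE]
    m <- tryCatch(solve(A, rep(1, length(keep))),
                  error = function(e) abort("singular first-passage system."))
    mfpt[keep, j] <- m
  }
  list(mfpt = mfpt, commute = mfpt + t(mfpt))
}
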