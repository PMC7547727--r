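#' Initialize parameters of the trajectory language model
#'
#' The model is: one-hot character -> embedding column (`M x N` matrix
#' \eqn{\Lambda}) -> single LSTM layer of `hidden_dim` units -> dense softmax
#' over the `N` characters. Gate weights are stored stacked by rows in the
#' order input gate, forget gate, candidate, output gate (`W` is `4L x M`,
#' `U` is `4L x L`, `b` length `4L`).
#'
#' Initialization: embedding entries uniform on (-0.05, 0.05); `W`, `U` and
#' the output weights `D` Glorot-uniform; biases zero except the forget-gate
#' bias, set to 1 (the usual guard against early forgetting). Draws come from
#' R's RNG, so call `set.seed()` first for reproducibility.
#'
#' @param n_labels alphabet size N.
#' @param embed_dim embedding dimension M (default 8).
#' @param hidden_dim LSTM units L (default 64).
#' @param init `"glorot"` (default) or `"zeros"` (useful in unit tests: the
#'   zero model predicts the uniform distribution).
#' @return A list of class `trajlm_params` with elements `embedding`, `W`,
#'   `U`, `b`, `D`, `b_d`.
#' @export
trajlm_params <- function(n_labels, embed_dim = 8, hidden_dim = 64,
                          init = c("glorot", "zeros")) {
  init <- match.arg(init)
  N <- as.integer(n_labels); M <- as.integer(embed_dim)
  L <- as.integer(hidden_dim)
  stopifnot(N >= 1, M >= 1, L >= 1)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- if (init == "zeros") {
    list(embedding = matrix(0, M, N), W = matrix(0, 4 * L, M),
         U = matrix(0, 4 * L, L), b = numeric(4 * L), D = matrix(0, N, L),
         b_d = numeric(N))
  } else {
    b <- numeric(4 * L)
    b[(L + 1):(2 * L)] <- 1  # forget-gate bias
    list(embedding = matrix(runif(M * N, -0.05, 0.05), M, N),
         W = glorot(4 * L, M), U = glorot(4 * L, L), b = b,
         D = glorot(N, L), b_d = numeric(N))
  }
  structure(p, dims = list(n_labels = N, embed_dim = M, hidden_dim = L),
            class = "trajlm_params")
}

param_dims <- function(params) {
  list(n_labels = ncol(params$embedding), embed_dim = nrow(params$embedding),
       hidden_dim = ncol(params$U))
}

#' Embed a one-hot character
#'
#' Returns \eqn{x = \Lambda s}, i.e. the embedding column selected by the
#' one-hot vector.
#'
#' @param params a `trajlm_params` (or fitted model's `$params`).
#' @param s one-hot numeric vector of length N (exactly one 1, rest 0).
#' @return Numeric embedding vector of length M.
#' @export
embed_onehot <- function(params, s) {
  if (length(s) != ncol(params$embedding) || any(!(s %in% c(0, 1))) ||
      sum(s) != 1)
    abort("`s` must be a one-hot vector of length `n_labels`.")
  as.numeric(params$embedding %*% s)
}

#' One LSTM update step
#'
#' Applies the gate equations: \eqn{f, i, o} by logistic sigmoid, candidate
#' \eqn{\tilde c} by tanh, \eqn{c \leftarrow f \circ c_{prev} + i \circ
#' \tilde c}, \eqn{h \leftarrow o \circ \tanh c}. This plain-R version is the
#' reference path for single steps; training uses the batched C++ kernel.
#'
#' @param params a `trajlm_params`.
#' @param x embedding vector of length M.
#' @param state list with `hidden` and `cell` vectors of length L (defaults to
#'   zeros).
#' @return List with `state` (new `hidden`/`cell`) and `h` (the output,
#'   identical to `state$hidden`).
#' @export
lstm_step <- function(params, x, state = NULL) {
  L <- ncol(params$U)
  if (length(x) != ncol(params$W))
    abort("`x` has the wrong length for the embedding dimension.")
  state <- state %||% list(hidden = numeric(L), cell = numeric(L))
  if (length(state$hidden) != L || length(state$cell) != L)
    abort("`state` vectors must have length `hidden_dim`.")
  a <- as.numeric(params$W %*% x + params$U %*% state$hidden + params$b)
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(a[1:L])
  f <- sig(a[(L + 1):(2 * L)])
  g <- tanh(a[(2 * L + 1):(3 * L)])
  o <- sig(a[(3 * L + 1):(4 * L)])
  cell <- f * state$cell + i * g
  h <- o * tanh(cell)
  list(state = list(hidden = h, cell = cell), h = h)
}

#' Output probabilities from a hidden state
#'
#' Softmax of the affine readout \eqn{\hat y = \mathrm{softmax}(D h + b_d)},
#' computed with max-subtraction for numerical stability.
#'
#' @param params a `trajlm_params`.
#' @param h hidden-state vector of length L.
#' @return Probability vector of length N (positive, sums to 1).
#' @export
output_probs <- function(params, h) {
  z <- as.numeric(params$D %*% h + params$b_d)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Teacher-forced cross-entropy of a label sequence
#'
#' Runs the model over `labels` from a zero initial state, scoring the
#' predicted distribution at each position against the next observed label.
#' The summed loss is \eqn{J = -\sum_t \ln \hat y^{(t)}[s^{(t+1)}]} in nats;
#' `per_symbol` is \eqn{J/T}, comparable to the entropy rate of the source.
#'
#' @param params a `trajlm_params` or a fitted `trajlm_fit`.
#' @param labels integer label vector (0-based), length at least 2.
#' @return List with `total` and `per_symbol` loss in nats.
#' @export
sequence_loss <- function(params, labels) {
  params <- as_trajlm_params(params)
  if (length(labels) < 2) abort("`labels` must contain at least 2 symbols.")
  check_labels(labels, ncol(params$embedding))
  cpp_sequence_loss(unclass(params), as.integer(labels))
}

#' Conditional next-character distribution
#'
#' Feeds `context` through the model from a zero initial state and returns
#' the predicted distribution of the next character, the learned
#' \eqn{Q(x^{(t+1)} \mid x^{(t)} \dots x^{(0)})}.
#'
#' @param object a fitted `trajlm_fit` or bare `trajlm_params`.
#' @param context integer label vector (0-based), length at least 1.
#' @return Probability vector of length N.
#' @export
conditional_probs <- function(object, context) {
  params <- as_trajlm_params(object)
  if (length(context) < 1) abort("`context` must contain at least 1 symbol.")
  check_labels(context, ncol(params$embedding))
  as.numeric(cpp_conditional_probs(unclass(params), as.integer(context)))
}

as_trajlm_params <- function(object) {
  if (inherits(object, "trajlm_fit")) return(object$params)
  if (inherits(object, "trajlm_params")) return(object)
  if (is.list(object) && all(c("embedding", "W", "U", "b", "D", "b_d") %in%
                             names(object)))
    return(object)
  abort("expected a `trajlm_fit` or `trajlm_params` object.")
}

check_labels <- function(labels, n_labels) {
  if (any(!is.finite(labels)))
    abort("labels must be finite integers.")
  if (any(labels < 0 | labels >= n_labels))
    abort(sprintf("labels must lie in [0, %d).", n_labels))
  invisible(labels)
}
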