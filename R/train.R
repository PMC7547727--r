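#' Fit the trajectory language model
#'
#' Splits the label series into non-overlapping windows of `seq_len` inputs
#' (plus a one-symbol lookahead for the teacher-forced targets), batches
#' them, and minimizes the summed next-character cross-entropy by gradient
#' descent. The hidden state is reset to zero at the start of every window,
#' windows are reshuffled each epoch, and the final `validation_fraction` of
#' the series (contiguous, never shuffled) is held out to monitor
#' generalization. Losses are reported per symbol in nats, directly
#' comparable to the entropy rate of the generating process.
#'
#' Defaults mirror the model-system configuration (`embed_dim = 8`,
#' `hidden_dim = 64`, `seq_len = 100`, `batch_size = 64`, 20 epochs);
#' biomolecular-scale series would use `embed_dim = 128`, `hidden_dim =
#' 1024`. The default optimizer is Adam (`learning_rate = 1e-3`) with
#' gradient clipping at global norm 5; set `optimizer = "sgd"` for plain
#' stochastic gradient descent.
#'
#' @param labels integer label vector (0-based) from [encode_series()] or
#'   [sample_chain()]; must contain at least `seq_len + 1` symbols.
#' @param n_labels alphabet size N; defaults to the attached scheme's
#'   `n_labels`, else `max(labels) + 1`.
#' @param embed_dim,hidden_dim embedding dimension M and LSTM units L.
#' @param seq_len,batch_size,epochs training-window length, batch size and
#'   number of epochs.
#' @param learning_rate step size (Adam default 1e-3; for `"sgd"` something
#'   like 0.5 is more appropriate).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed integer seed governing initialization and epoch shuffling.
#' @param validation_fraction fraction (in `[0, 1)`) of the series tail held
#'   out for validation.
#' @param clip_norm gradient clipping threshold (global L2 norm; 0 disables).
#' @return An object of class `trajlm_fit`: a list with `params`
#'   (`trajlm_params`), `dims`, `history` (tibble of per-epoch `train_loss` /
#'   `val_loss`), `config`, `scheme` (if attached to `labels`), and
#'   `seed_context` (a training window reused as the default generation
#'   context).
#' @seealso [sample_trajectory()], [conditional_probs()], [tidy.trajlm_fit()]
#' @export
train_trajlm <- function(labels, n_labels = NULL, embed_dim = 8,
                         hidden_dim = 64, seq_len = 100, batch_size = 64,
                         epochs = 20, learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"), seed = 1,
                         validation_fraction = 0.1, clip_norm = 5) {
  optimizer <- match.arg(optimizer)
  scheme <- attr(labels, "scheme")
  n_labels <- n_labels %||% (if (!is.null(scheme)) scheme$n_labels
                             else max(labels) + 1L)
  labels <- as.integer(labels)
  check_labels(labels, n_labels)
  if (seq_len < 2) abort("`seq_len` must be at least 2.")
  if (length(labels) < seq_len + 1)
    abort("`labels` must contain at least `seq_len + 1` symbols.")
  if (validation_fraction < 0 || validation_fraction >= 1)
    abort("`validation_fraction` must lie in [0, 1).")
  if (epochs < 1 || batch_size < 1) abort("`epochs`/`batch_size` must be >= 1.")

  set.seed(seed)
  params0 <- trajlm_params(n_labels, embed_dim, hidden_dim)
  res <- cpp_train(labels, unclass(params0), as.integer(seq_len),
                   as.integer(batch_size), as.integer(epochs), learning_rate,
                   optimizer, validation_fraction, clip_norm)
  params <- structure(res$params,
                      dims = attr(params0, "dims"), class = "trajlm_params")
  n_train <- floor(length(labels) * (1 - validation_fraction))
  ctx_start <- if (n_train > seq_len)
    sample.int(n_train - seq_len, 1) else 1L
  structure(
    list(params = params,
         dims = attr(params0, "dims"),
         history = tibble::tibble(epoch = seq_len(epochs),
                                  train_loss = res$train_loss,
                                  val_loss = res$val_loss),
         config = list(seq_len = seq_len, batch_size = batch_size,
                       epochs = epochs, learning_rate = learning_rate,
                       optimizer = optimizer, seed = seed,
                       validation_fraction = validation_fraction,
                       clip_norm = clip_norm,
                       n_train_windows = res$n_train_windows,
                       n_val_windows = res$n_val_windows),
         scheme = scheme,
         seed_context = labels[ctx_start:(ctx_start + seq_len - 1)]),
    class = "trajlm_fit")
}

#' @export
print.trajlm_fit <- function(x, ...) {
  d <- x$dims
  h <- x$history
  cat(sprintf(
    "<trajlm_fit> N = %d labels, M = %d, L = %d | %d epoch(s), %s\n",
    d$n_labels, d$embed_dim, d$hidden_dim, nrow(h), x$config$optimizer))
  cat(sprintf("  final loss (nats/symbol): train %.4f, validation %s\n",
              h$train_loss[nrow(h)],
              ifelse(is.na(h$val_loss[nrow(h)]), "NA",
                     sprintf("%.4f", h$val_loss[nrow(h)]))))
  invisible(x)
}

#' Tidy the training history of a fitted trajectory language model
#'
#' @param x a `trajlm_fit`.
#' @param ... unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss` (nats per symbol).
#' @export
tidy.trajlm_fit <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x a `trajlm_fit`.
#' @param ... unused.
#' @return A one-row tibble: dimensions, parameter count, final losses.
#' @export
glance.trajlm_fit <- function(x, ...) {
  d <- x$dims
  n_par <- with(d, embed_dim * n_labels +
                  4 * hidden_dim * (embed_dim + hidden_dim + 1) +
                  n_labels * (hidden_dim + 1))
  h <- x$history
  tibble::tibble(n_labels = d$n_labels, embed_dim = d$embed_dim,
                 hidden_dim = d$hidden_dim, n_parameters = n_par,
                 epochs = nrow(h),
                 train_loss = h$train_loss[nrow(h)],
                 val_loss = h$val_loss[nrow(h)])
}
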