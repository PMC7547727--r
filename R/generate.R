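#' Generate a synthetic label trajectory from a fitted model
#'
#' Autoregressive sampling at temperature 1: the seed context is fed through
#' the network, then each next character is drawn from the predicted
#' categorical distribution and fed back. The first `burn_in` sampled symbols
#' are discarded to wash out initial-state transients. Unbiased (temperature
#' 1) sampling is deliberate: the Boltzmann and kinetics checks require
#' sampling the learned conditional law, not its mode.
#'
#' @param fit a `trajlm_fit` (or bare `trajlm_params`).
#' @param length number of symbols to return.
#' @param seed_context integer label vector used to prime the state; defaults
#'   to the training window stored in the fit, else a single uniformly drawn
#'   label.
#' @param burn_in symbols discarded before recording (default 1000).
#' @param rng_seed optional integer; when given, `set.seed(rng_seed)` makes
#'   the draw reproducible.
#' @return Integer label vector (0-based) of the requested length, with the
#'   fit's discretization scheme attached when available.
#' @export
sample_trajectory <- function(fit, length, seed_context = NULL,
                              burn_in = 1000, rng_seed = NULL) {
  params <- as_trajlm_params(fit)
  N <- ncol(params$embedding)
  if (length < 1) abort("`length` must be at least 1.")
  if (burn_in < 0) abort("`burn_in` must be non-negative.")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(seed_context) && inherits(fit, "trajlm_fit"))
    seed_context <- fit$seed_context
  if (is.null(seed_context))
    seed_context <- sample.int(N, 1) - 1L
  if (any(seed_context < 0 | seed_context >= N))
    abort("`seed_context` labels do not match the model's alphabet size.")
  out <- as.integer(cpp_sample(unclass(params), as.integer(seed_context),
                               length, as.integer(burn_in)))
  if (inherits(fit, "trajlm_fit") && !is.null(fit$scheme))
    attr(out, "scheme") <- fit$scheme
  out
}

#' Decode a generated label trajectory to order-parameter values
#'
#' Thin wrapper over [decode_labels()] so generated series can be analyzed
#' exactly like real ones.
#'
#' @inheritParams decode_labels
#' @export
decode_trajectory <- function(labels, scheme = attr(labels, "scheme")) {
  decode_labels(labels, scheme)
}
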