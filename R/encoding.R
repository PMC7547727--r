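#' Fit a spatial discretization scheme
#'
#' Divides the observed range `[min(series), max(series)]` into `n_labels`
#' equal-width bins; each bin's representative value is its midpoint. This is
#' the "alphabet" of the trajectory language model: every sample is replaced
#' by the character (bin index) whose representative value is nearest.
#'
#' @param series numeric series (finite, non-constant).
#' @param n_labels number of bins \eqn{N \ge 2}.
#' @return An object of class `discretization_scheme` with fields `n_labels`,
#'   `lo`, `hi`, `bin_width`, and `representatives` (length-`N` midpoints).
#' @examples
#' sc <- fit_scheme(c(0, 1), n_labels = 2)
#' sc$representatives  # 0.25 0.75
#' @export
fit_scheme <- function(series, n_labels) {
  if (length(series) == 0 || !all(is.finite(series)))
    abort("`series` must be non-empty and finite.")
  if (n_labels < 2) abort("`n_labels` must be at least 2.")
  lo <- min(series); hi <- max(series)
  if (lo == hi) abort("degenerate range: `series` is constant, cannot bin.")
  n_labels <- as.integer(n_labels)
  w <- (hi - lo) / n_labels
  structure(list(n_labels = n_labels, lo = lo, hi = hi, bin_width = w,
                 representatives = lo + w * (seq_len(n_labels) - 0.5)),
            class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat(sprintf("<discretization_scheme> N = %d bins on [%g, %g], width %g\n",
              x$n_labels, x$lo, x$hi, x$bin_width))
  invisible(x)
}

#' Encode a series as integer labels
#'
#' Bins are half-open `[edge_i, edge_{i+1})` except the last, which is closed;
#' values outside `[lo, hi]` clamp to the end bins. Labels are 0-based
#' (0 ... N-1), matching the one-hot character convention.
#'
#' @param series numeric series (finite).
#' @param scheme a [fit_scheme()] result.
#' @return Integer vector of labels in `[0, N)` with the scheme attached as
#'   attribute `"scheme"`.
#' @export
encode_series <- function(series, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  bad <- which(!is.finite(series))
  if (length(bad))
    abort(sprintf("non-finite value at index %d cannot be encoded.", bad[1]))
  idx <- floor((series - scheme$lo) / scheme$bin_width)
  idx <- pmin(pmax(idx, 0), scheme$n_labels - 1)
  out <- as.integer(idx)
  attr(out, "scheme") <- scheme
  out
}

#' Decode labels back to representative values
#'
#' @param labels integer labels in `[0, N)`.
#' @param scheme a [fit_scheme()] result (defaults to the scheme attached to
#'   `labels`).
#' @return Numeric vector of bin-midpoint representative values.
#' @export
decode_labels <- function(labels, scheme = attr(labels, "scheme")) {
  if (is.null(scheme)) abort("no `scheme` supplied or attached to `labels`.")
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (length(labels) == 0) return(numeric(0))
  if (any(labels < 0 | labels >= scheme$n_labels))
    abort("labels out of range for the scheme.")
  scheme$representatives[as.integer(labels) + 1L]
}

#' One-hot encode labels
#'
#' @param labels integer labels in `[0, n_labels)`.
#' @param n_labels alphabet size N.
#' @return A `length(labels)` x `n_labels` binary matrix; row `t` has a single
#'   1 in column `labels[t] + 1`.
#' @export
one_hot <- function(labels, n_labels) {
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= n_labels))
    abort("labels out of range [0, n_labels).")
  m <- matrix(0, nrow = length(labels), ncol = n_labels)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Write / read a label series with its sidecar manifest
#'
#' Labels are written one integer per line; the discretization scheme (N, lo,
#' hi) goes to a JSON manifest at `<path>.json` so decoding stays
#' reproducible.
#'
#' @param labels integer label vector, ideally with a scheme attribute.
#' @param path label file path.
#' @param scheme optional scheme (defaults to the one attached to `labels`).
#' @export
write_labels <- function(labels, path, scheme = attr(labels, "scheme")) {
  writeLines(as.character(as.integer(labels)), path)
  if (!is.null(scheme))
    jsonlite::write_json(list(n_labels = scheme$n_labels, lo = scheme$lo,
                              hi = scheme$hi),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  labels <- as.integer(readLines(path))
  manifest <- paste0(path, ".json")
  if (file.exists(manifest)) {
    m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    w <- (m$hi - m$lo) / m$n_labels
    attr(labels, "scheme") <- structure(
      list(n_labels = as.integer(m$n_labels), lo = m$lo, hi = m$hi,
           bin_width = w,
           representatives = m$lo + w * (seq_len(m$n_labels) - 0.5)),
      class = "discretization_scheme")
  }
  labels
}
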