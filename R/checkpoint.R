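#' Save / load a fitted model as a plain-text checkpoint
#'
#' The checkpoint is a directory holding `manifest.json` (dimensions,
#' training configuration, discretization scheme, package version) and
#' `params.json` (all weight matrices, written at full double precision), so
#' a reloaded model reproduces losses and samples exactly and generated
#' labels can be decoded without the original session.
#'
#' @param fit a `trajlm_fit`.
#' @param dir checkpoint directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajlm <- function(fit, dir) {
  stopifnot(inherits(fit, "trajlm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "trajlm",
    version = as.character(utils::packageVersion("trajlm")),
    dims = fit$dims, config = fit$config,
    scheme = if (!is.null(fit$scheme))
      fit$scheme[c("n_labels", "lo", "hi")],
    seed_context = fit$seed_context,
    history = as.list(fit$history))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(fit$params), file.path(dir, "params.json"),
                       digits = NA)
  invisible(dir)
}

#' @rdname write_trajlm
#' @export
read_trajlm <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  p <- jsonlite::read_json(file.path(dir, "params.json"),
                           simplifyVector = TRUE)
  p$b <- as.numeric(p$b); p$b_d <- as.numeric(p$b_d)
  dims <- list(n_labels = as.integer(m$dims$n_labels),
               embed_dim = as.integer(m$dims$embed_dim),
               hidden_dim = as.integer(m$dims$hidden_dim))
  scheme <- NULL
  if (!is.null(m$scheme) && length(m$scheme)) {
    w <- (m$scheme$hi - m$scheme$lo) / m$scheme$n_labels
    scheme <- structure(
      list(n_labels = as.integer(m$scheme$n_labels), lo = m$scheme$lo,
           hi = m$scheme$hi, bin_width = w,
           representatives = m$scheme$lo + w *
             (seq_len(m$scheme$n_labels) - 0.5)),
      class = "discretization_scheme")
  }
  structure(
    list(params = structure(p, dims = dims, class = "trajlm_params"),
         dims = dims, history = tibble::as_tibble(m$history),
         config = m$config, scheme = scheme,
         seed_context = as.integer(m$seed_context)),
    class = "trajlm_fit")
}
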