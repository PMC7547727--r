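#' Simulate overdamped Langevin dynamics on a model potential
#'
#' Integrates the overdamped (Brownian) Euler--Maruyama update
#' \deqn{x \leftarrow x - \nabla U\, \mathrm{d}t + \sqrt{2\,\mathrm{d}t/\beta}\,\eta}
#' with unit friction and unit mass, \eqn{\eta} standard normal per coordinate
#' per step. `beta = Inf` turns the noise off (deterministic gradient
#' descent), which is occasionally useful for checking fixed points.
#'
#' @param potential a [model_potential()].
#' @param beta inverse temperature \eqn{1/k_B T} (> 0, possibly `Inf`).
#' @param dt integration timestep (default 0.01).
#' @param n_steps number of integration steps (default 5e6).
#' @param save_stride keep every `save_stride`-th frame (default 10).
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   trajectory is bitwise reproducible.
#' @param initial_point length-2 numeric start point; defaults to the deepest
#'   well center of the potential.
#' @return A tibble of class `langevin_trajectory` with columns `time`
#'   (units of `dt`), `x`, `y`.
#' @examples
#' p <- builtin_potential("linear3")
#' traj <- simulate_langevin(p, beta = 9.5, n_steps = 1e4, seed = 1)
#' head(traj)
#' @export
simulate_langevin <- function(potential, beta, dt = 0.01, n_steps = 5e6,
                              save_stride = 10, seed = NULL,
                              initial_point = NULL) {
  stopifnot(inherits(potential, "model_potential"))
  if (!is.numeric(beta) || beta <= 0) abort("`beta` must be positive.")
  if (dt <= 0) abort("`dt` must be positive.")
  if (n_steps < 1) abort("`n_steps` must be at least 1.")
  if (save_stride < 1) abort("`save_stride` must be at least 1.")
  initial_point <- initial_point %||% deepest_minimum(potential)
  if (!is.null(seed)) set.seed(seed)
  g <- potential$gaussians
  res <- cpp_langevin(potential$confinement_weight,
                      potential$confinement_degree,
                      cbind(g$center_x, g$center_y), g$sign, g$width,
                      beta, dt, n_steps, as.integer(save_stride),
                      initial_point[1], initial_point[2])
  n_out <- length(res$x)
  out <- tibble::tibble(time = dt * save_stride * seq_len(n_out),
                        x = as.numeric(res$x), y = as.numeric(res$y))
  class(out) <- c("langevin_trajectory", class(out))
  out
}

#' Project a 2-D trajectory onto one coordinate
#'
#' @param trajectory a tibble with `x` and `y` columns, e.g. from
#'   [simulate_langevin()].
#' @param axis `"x"` or `"y"`.
#' @return Numeric vector of the chosen coordinate series.
#' @export
project_trajectory <- function(trajectory, axis = c("x", "y")) {
  axis <- match.arg(axis)
  trajectory[[axis]]
}

#' Write / read a trajectory as tab-delimited text
#'
#' One header line, then `time<TAB>x<TAB>y`.
#'
#' @param trajectory trajectory tibble.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  class(out) <- c("langevin_trajectory", class(out))
  out
}
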