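#' Construct a 2-D model potential
#'
#' A model potential is the sum of an even-degree polynomial confinement
#' \eqn{W (x^d + y^d)} and a set of signed, axis-separable Gaussian terms
#' \eqn{s_i\, G(x; cx_i)\, G(y; cy_i)} with
#' \eqn{G(x; c) = \exp\{-(x-c)^2 / (2\sigma^2)\}}. Attractive wells carry sign
#' \eqn{-1}; repulsive bumps carry sign \eqn{+1}.
#'
#' @param confinement_weight positive scalar \eqn{W}.
#' @param confinement_degree even integer degree \eqn{d} of the confinement.
#' @param gaussians data frame with columns `center_x`, `center_y`, `sign`
#'   (+1 or -1) and `width` (Gaussian \eqn{\sigma > 0}); may have zero rows
#'   for a pure confinement (useful for harmonic test potentials).
#' @param name label used in printing.
#' @return An object of class `model_potential`.
#' @seealso [builtin_potential()] for the three ready-made multi-well systems.
#' @export
model_potential <- function(confinement_weight, confinement_degree,
                            gaussians = NULL, name = "custom") {
  if (!is.numeric(confinement_weight) || confinement_weight <= 0)
    abort("`confinement_weight` must be a positive number.")
  if (confinement_degree %% 2 != 0 || confinement_degree < 2)
    abort("`confinement_degree` must be a positive even integer.")
  if (is.null(gaussians))
    gaussians <- tibble::tibble(center_x = double(), center_y = double(),
                                sign = double(), width = double())
  gaussians <- tibble::as_tibble(gaussians)
  stopifnot(all(c("center_x", "center_y", "sign", "width") %in% names(gaussians)))
  if (nrow(gaussians) > 0) {
    if (!all(gaussians$sign %in% c(-1, 1)))
      abort("Gaussian `sign` entries must be +1 or -1.")
    if (!all(gaussians$width > 0))
      abort("Gaussian `width` entries must be positive.")
  }
  structure(
    list(name = name, confinement_weight = confinement_weight,
         confinement_degree = as.integer(confinement_degree),
         gaussians = gaussians),
    class = "model_potential")
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("<model_potential: %s>  U = %g (x^%d + y^%d) %s\n", x$name,
              x$confinement_weight, x$confinement_degree,
              x$confinement_degree,
              if (nrow(x$gaussians)) sprintf("+ %d Gaussian term(s)",
                                             nrow(x$gaussians)) else ""))
  if (nrow(x$gaussians)) print(x$gaussians)
  invisible(x)
}

#' Built-in model potentials
#'
#' Three 2-D benchmark landscapes: a linear three-state system (collinear
#' wells A-B-C), a triangular three-state system (mutually adjacent wells),
#' and a four-state system with a central repulsive bump and four wells placed
#' antisymmetrically about the origin. The four-state geometry is fixed;
#' the three-state well placements default to `(-2, 0), (0, 0), (2, 0)`
#' (linear) and `(-2, 0), (2, 0), (0, 2.5)` (triangular) and can be
#' overridden via `centers`.
#'
#' @param name one of `"linear3"`, `"triangular3"`, `"four_state"`.
#' @param centers optional 2-column matrix of well centers overriding the
#'   default placements (wells only; the four-state central bump stays fixed).
#' @param sigma Gaussian width shared by all terms (default 0.8).
#' @param confinement_weight confinement prefactor \eqn{W} (default 1e-4).
#' @return A [model_potential()].
#' @examples
#' p <- builtin_potential("four_state")
#' potential_energy(p, 0, 0)
#' @export
builtin_potential <- function(name = c("linear3", "triangular3", "four_state"),
                              centers = NULL, sigma = 0.8,
                              confinement_weight = 1e-4) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(paste0(
                     "Unknown potential `", name[1],
                     "`; expected one of linear3, triangular3, four_state.")))
  # triangular: equilateral (side 4, centroid at the origin) so that all
  # three well pairs are equally distant in 2-D while the x-projections
  # (-2, 0, 2) coincide with the linear system's
  default_centers <- switch(name,
    linear3     = rbind(c(-2, 0), c(0, 0), c(2, 0)),
    triangular3 = rbind(c(-2, -2 / sqrt(3)), c(2, -2 / sqrt(3)),
                        c(0, 4 / sqrt(3))),
    four_state  = rbind(c(2, -1), c(0.5, 2), c(-0.5, -2), c(-2, 1)))
  centers <- centers %||% default_centers
  centers <- as.matrix(centers)
  g <- tibble::tibble(center_x = centers[, 1], center_y = centers[, 2],
                      sign = -1, width = sigma)
  if (name == "four_state")
    g <- dplyr::bind_rows(
      tibble::tibble(center_x = 0, center_y = 0, sign = 1, width = sigma), g)
  degree <- if (name == "four_state") 4L else 6L
  model_potential(confinement_weight, degree, g, name = name)
}

#' Potential energy
#'
#' Evaluates \eqn{U(x, y)} of a [model_potential()]; vectorized over `x`, `y`.
#'
#' @param potential a `model_potential`.
#' @param x,y coordinates (recycled to common length).
#' @return Numeric vector of energies.
#' @export
potential_energy <- function(potential, x, y) {
  stopifnot(inherits(potential, "model_potential"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  u <- potential$confinement_weight *
    (x^potential$confinement_degree + y^potential$confinement_degree)
  g <- potential$gaussians
  for (i in seq_len(nrow(g))) {
    u <- u + g$sign[i] *
      exp(-((x - g$center_x[i])^2 + (y - g$center_y[i])^2) / (2 * g$width[i]^2))
  }
  u
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return A tibble with columns `dU_dx`, `dU_dy` (one row per input point).
#' @export
potential_gradient <- function(potential, x, y) {
  stopifnot(inherits(potential, "model_potential"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  d <- potential$confinement_degree
  gx <- potential$confinement_weight * d * x^(d - 1)
  gy <- potential$confinement_weight * d * y^(d - 1)
  g <- potential$gaussians
  for (i in seq_len(nrow(g))) {
    s2 <- g$width[i]^2
    dx <- x - g$center_x[i]; dy <- y - g$center_y[i]
    e <- g$sign[i] * exp(-(dx^2 + dy^2) / (2 * s2))
    gx <- gx - e * dx / s2
    gy <- gy - e * dy / s2
  }
  tibble::tibble(dU_dx = gx, dU_dy = gy)
}

#' Read a model potential from a JSON config file
#'
#' The file holds `name`, `confinement_weight`, `confinement_degree`, and a
#' `gaussians` array of records with `center_x`, `center_y`, `sign`, `width`.
#'
#' @param path file path.
#' @return A [model_potential()].
#' @export
read_potential <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_potential(cfg$confinement_weight, cfg$confinement_degree,
                  tibble::as_tibble(cfg$gaussians),
                  name = cfg$name %||% "config")
}

#' @rdname read_potential
#' @param potential a `model_potential` to serialize.
#' @export
write_potential <- function(potential, path) {
  stopifnot(inherits(potential, "model_potential"))
  jsonlite::write_json(
    list(name = potential$name,
         confinement_weight = potential$confinement_weight,
         confinement_degree = potential$confinement_degree,
         gaussians = potential$gaussians),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# deepest attractive well center (used as the default Langevin start)
deepest_minimum <- function(potential) {
  g <- dplyr::filter(potential$gaussians, .data$sign < 0)
  if (nrow(g) == 0) return(c(0, 0))
  u <- potential_energy(potential, g$center_x, g$center_y)
  c(g$center_x[which.min(u)], g$center_y[which.min(u)])
}
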