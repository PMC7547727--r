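#' Plot a Langevin trajectory
#'
#' @param object a `langevin_trajectory` tibble.
#' @param ... unused.
#' @return A ggplot: both coordinates against time.
#' @export
autoplot.langevin_trajectory <- function(object, ...) {
  tidyr::pivot_longer(object, c("x", "y"), names_to = "coordinate") |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~coordinate, ncol = 1) +
    ggplot2::labs(x = "time", y = "coordinate")
}

#' Plot training history
#'
#' @param object a `trajlm_fit`.
#' @param ... unused.
#' @return A ggplot of per-symbol train/validation loss by epoch.
#' @export
autoplot.trajlm_fit <- function(object, ...) {
  tidyr::pivot_longer(object$history, -"epoch", names_to = "series") |>
    dplyr::filter(is.finite(.data$value)) |>
    ggplot2::ggplot(ggplot2::aes(.data$epoch, .data$value,
                                 colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(y = "loss (nats / symbol)", colour = NULL)
}

#' Plot state occupancies
#'
#' @param object a [state_probabilities()] tibble.
#' @param ... unused.
#' @return A ggplot with 1-standard-error bars.
#' @export
autoplot.state_probabilities <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$state),
                                       .data$probability)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$probability - .data$se,
                                        ymax = .data$probability + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "state", y = "occupancy probability")
}

#' Plot a commit curve
#'
#' @param object a [commit_curve()] tibble.
#' @param ... unused.
#' @return A ggplot faceted by ordered state pair, counts with 1-SE ribbons.
#' @export
autoplot.commit_curve <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pair = paste0(.data$from, "→", .data$to))
  ggplot2::ggplot(df, ggplot2::aes(.data$commit_time, .data$count_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$count_mean - .data$count_se,
                                      ymax = .data$count_mean + .data$count_se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "commit time (samples)",
                  y = "transitions per segment")
}

#' Compare two commit curves (e.g. input data versus generated data)
#'
#' @param reference,generated [commit_curve()] tibbles on the same state map
#'   and commit-time grid.
#' @param labels length-2 character vector naming the two sources.
#' @return A ggplot overlaying both curves per ordered state pair.
#' @export
plot_commit_comparison <- function(reference, generated,
                                   labels = c("reference", "generated")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(reference), source = labels[1]),
    dplyr::mutate(tibble::as_tibble(generated), source = labels[2])) |>
    dplyr::mutate(pair = paste0(.data$from, "→", .data$to))
  ggplot2::ggplot(df, ggplot2::aes(.data$commit_time, .data$count_mean,
                                   colour = .data$source,
                                   fill = .data$source)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$count_mean - .data$count_se,
                                      ymax = .data$count_mean + .data$count_se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "commit time (samples)", y = "transitions per segment",
                  colour = NULL, fill = NULL)
}

#' Plot embedding versus counted kinetic distances
#'
#' @param object a [kinetic_distance_table()].
#' @param ... unused.
#' @return A ggplot of the rescaled distances per unordered state pair.
#' @export
autoplot.kinetic_distance_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pair = paste0(.data$state_l, "–", .data$state_m)) |>
    tidyr::pivot_longer(c("t_rescaled", "tau_rescaled"),
                        names_to = "method", values_to = "distance") |>
    dplyr::mutate(method = dplyr::recode(.data$method,
                                         t_rescaled = "embedding (model)",
                                         tau_rescaled = "counted (data)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$distance,
                                   shape = .data$method)) +
    ggplot2::geom_point(size = 3, position =
                          ggplot2::position_dodge(width = 0.2)) +
    ggplot2::labs(x = "state pair", y = "rescaled kinetic distance",
                  shape = NULL)
}
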