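#' Map discretization labels to metastable states
#'
#' A label is assigned to state `s` when its representative value lies within
#' `radius` of minimum `s`'s projected coordinate; when several minima
#' qualify the nearer one wins, exact ties resolve to the lower state id
#' (reported via a message). Labels near barriers fall outside every radius
#' and stay unassigned (`NA`): they are skipped, not treated as a state.
#'
#' @param scheme a [fit_scheme()] discretization.
#' @param minima_projections projected (1-D) coordinates of the free-energy
#'   minima, one per state, in state-id order.
#' @param radius assignment radius around each minimum (same units as the
#'   order parameter).
#' @return An object of class `state_map`: list with `n_states`,
#'   `assignment` (length-N integer vector of 0-based state ids, `NA` =
#'   unassigned), `minima`, `radius`.
#' @export
assign_states <- function(scheme, minima_projections, radius = 0.5) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (anyDuplicated(minima_projections)) abort("minima must be distinct.")
  if (radius <= 0) abort("`radius` must be positive.")
  reps <- scheme$representatives
  assignment <- rep(NA_integer_, scheme$n_labels)
  tied <- FALSE
  for (i in seq_along(reps)) {
    d <- abs(reps[i] - minima_projections)
    if (min(d) <= radius) {
      hits <- which(d == min(d))
      if (length(hits) > 1) tied <- TRUE
      assignment[i] <- hits[1] - 1L
    }
  }
  if (tied)
    inform("equal-distance tie(s) resolved to the lower state id.")
  structure(list(n_states = length(minima_projections),
                 assignment = assignment,
                 minima = as.numeric(minima_projections), radius = radius),
            class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  cat(sprintf("<state_map> %d states over %d labels (%d unassigned)\n",
              x$n_states, length(x$assignment), sum(is.na(x$assignment))))
  invisible(x)
}

# per-sample state series (NA where unassigned)
state_series <- function(labels, statemap) {
  statemap$assignment[as.integer(labels) + 1L]
}

segment_indices <- function(n, n_segments) {
  bounds <- floor(seq(0, n, length.out = n_segments + 1))
  purrr::map(seq_len(n_segments), ~ seq(bounds[.x] + 1, bounds[.x + 1]))
}

#' Boltzmann state occupancies with segment standard errors
#'
#' Occupancy fraction of each state among the assigned samples, averaged over
#' `n_segments` equal contiguous segments; the standard error is the
#' population SD over segments divided by `sqrt(n_segments)`.
#'
#' @param labels integer label series (0-based).
#' @param statemap an [assign_states()] map.
#' @param n_segments number of contiguous segments (>= 2).
#' @return A tibble of class `state_probabilities` with columns `state`,
#'   `probability`, `se`.
#' @export
state_probabilities <- function(labels, statemap, n_segments = 20) {
  if (n_segments < 2) abort("`n_segments` must be at least 2.")
  states <- state_series(labels, statemap)
  segs <- segment_indices(length(states), n_segments)
  ns <- statemap$n_states
  pmat <- vapply(seq_along(segs), function(i) {
    s <- states[segs[[i]]]
    s <- s[!is.na(s)]
    if (length(s) == 0)
      abort(sprintf("segment %d contains no assigned samples.", i))
    tabulate(s + 1L, ns) / length(s)
  }, numeric(ns))
  out <- tibble::tibble(
    state = seq_len(ns) - 1L,
    probability = rowMeans(pmat),
    se = apply(pmat, 1, function(v) sqrt(mean((v - mean(v))^2))) /
      sqrt(n_segments))
  class(out) <- c("state_probabilities", class(out))
  out
}

#' Free energy from occupancy probabilities
#'
#' \eqn{F_i = -\ln(P_i) / \beta}. Zero probabilities give `Inf` (with a
#' warning) rather than an error, since empty states are informative.
#'
#' @param probabilities numeric probability vector, or a
#'   [state_probabilities()] tibble (a `free_energy` column is appended).
#' @param beta inverse temperature.
#' @return Numeric vector, or the input tibble with a `free_energy` column.
#' @export
free_energy <- function(probabilities, beta) {
  if (is.data.frame(probabilities)) {
    probabilities$free_energy <- free_energy(probabilities$probability, beta)
    return(probabilities)
  }
  if (any(probabilities < 0)) abort("probabilities must be non-negative.")
  if (any(probabilities == 0))
    warn("zero probabilities produce infinite free energies.")
  -log(probabilities) / beta
}

# run-length encoding of the assigned-state sequence (unassigned skipped)
state_runs <- function(labels, statemap) {
  s <- state_series(labels, statemap)
  s <- s[!is.na(s)]
  if (length(s) == 0) return(list(values = integer(0), lengths = integer(0)))
  r <- rle(s)
  list(values = r$values, lengths = r$lengths)
}

# committed state sequence at one commit time: drop runs shorter than
# `commit_time`, then merge consecutive equal survivors
committed_states <- function(runs, commit_time) {
  v <- runs$values[runs$lengths >= commit_time]
  if (length(v) <= 1) return(v)
  v[c(TRUE, v[-1] != v[-length(v)])]
}

count_ordered <- function(cv, n_states) {
  counts <- matrix(0, n_states, n_states)
  if (length(cv) >= 2) {
    from <- cv[-length(cv)] + 1L
    to <- cv[-1] + 1L
    for (i in seq_along(from)) counts[from[i], to[i]] <-
        counts[from[i], to[i]] + 1
  }
  counts
}

ordered_pair_grid <- function(n_states) {
  g <- expand.grid(from = seq_len(n_states) - 1L, to = seq_len(n_states) - 1L)
  g <- g[g$from != g$to, ]
  tibble::as_tibble(g[order(g$from, g$to), ])
}

#' Commit-time transition counts
#'
#' Maps the label series to states (unassigned samples are skipped),
#' compresses it to runs of consecutive identical states, keeps only runs of
#' length at least `commit_time` ("committed" visits), and counts ordered
#' transitions between consecutive committed runs with different states.
#'
#' @inheritParams state_probabilities
#' @param commit_time minimum residence time, in samples (>= 1).
#' @return A tibble with columns `from`, `to` (0-based state ids) and
#'   `count`, one row per ordered pair.
#' @examples
#' sc <- fit_scheme(c(0, 1), 2)
#' sm <- assign_states(sc, c(0.25, 0.75), radius = 0.3)
#' commit_transitions(c(0, 0, 0, 1, 0, 1, 1, 1), sm, commit_time = 2)
#' @export
commit_transitions <- function(labels, statemap, commit_time) {
  if (commit_time < 1) abort("`commit_time` must be at least 1 sample.")
  runs <- state_runs(labels, statemap)
  cv <- committed_states(runs, commit_time)
  counts <- count_ordered(cv, statemap$n_states)
  g <- ordered_pair_grid(statemap$n_states)
  g$count <- counts[cbind(g$from + 1L, g$to + 1L)]
  g
}

#' Commit curve: transition counts versus commit time, with standard errors
#'
#' Computes [commit_transitions()] on each of `n_segments` equal contiguous
#' segments for every commit time on the grid, and reports the per-segment
#' mean and standard error (population SD over segments / `sqrt(n)`).
#'
#' @inheritParams state_probabilities
#' @param commit_times increasing integer grid of commit times (samples).
#' @return A tibble of class `commit_curve` with columns `from`, `to`,
#'   `commit_time`, `count_mean`, `count_se`. With a single segment the
#'   standard error is undefined and reported as `NA` (with a warning).
#' @export
commit_curve <- function(labels, statemap, commit_times = 1:200,
                         n_segments = 20) {
  if (is.unsorted(commit_times, strictly = TRUE))
    abort("`commit_times` must be strictly increasing.")
  if (n_segments < 1) abort("`n_segments` must be at least 1.")
  if (n_segments == 1)
    warn("single segment: standard errors are undefined (NA).")
  ns <- statemap$n_states
  segs <- segment_indices(length(labels), n_segments)
  # counts[pair, commit_time, segment]
  g <- ordered_pair_grid(ns)
  arr <- array(0, dim = c(nrow(g), length(commit_times), n_segments))
  for (k in seq_along(segs)) {
    runs <- state_runs(labels[segs[[k]]], statemap)
    for (j in seq_along(commit_times)) {
      counts <- count_ordered(committed_states(runs, commit_times[j]), ns)
      arr[, j, k] <- counts[cbind(g$from + 1L, g$to + 1L)]
    }
  }
  out <- tidyr::crossing(g, commit_time = as.integer(commit_times)) |>
    dplyr::arrange(.data$from, .data$to, .data$commit_time)
  idx <- cbind(rep(seq_len(nrow(g)), each = length(commit_times)),
               rep(seq_along(commit_times), times = nrow(g)))
  out$count_mean <- apply(arr, c(1, 2), mean)[idx]
  out$count_se <- if (n_segments == 1) NA_real_ else
    (apply(arr, c(1, 2), function(v) sqrt(mean((v - mean(v))^2))) /
       sqrt(n_segments))[idx]
  attr(out, "n_segments") <- n_segments
  class(out) <- c("commit_curve", class(out))
  out
}

#' Embedding-layer transition-probability ansatz
#'
#' From the embedding matrix \eqn{\Lambda} (columns \eqn{x_k}), forms
#' \deqn{Q_{lm} = \exp(x_m \cdot x_l) / \sum_k \exp(x_k \cdot x_l),}
#' the softmax over destination characters of the embedding dot products.
#' Rows sum to one exactly.
#'
#' @param embedding an `M x N` embedding matrix, or a `trajlm_fit` (its
#'   embedding is used).
#' @return An `N x N` row-stochastic matrix.
#' @export
embedding_transition_matrix <- function(embedding) {
  if (inherits(embedding, "trajlm_fit") || inherits(embedding, "trajlm_params"))
    embedding <- as_trajlm_params(embedding)$embedding
  gram <- crossprod(embedding)  # (l, m) = x_l . x_m
  z <- exp(gram - apply(gram, 1, max))
  z / rowSums(z)
}

#' Empirical label occupancies
#'
#' @param labels integer label series (0-based).
#' @param n_labels alphabet size.
#' @return Numeric vector of length `n_labels` summing to 1.
#' @export
label_occupancy <- function(labels, n_labels) {
  tabulate(as.integer(labels) + 1L, n_labels) / length(labels)
}

state_label_sets <- function(statemap) {
  purrr::map(seq_len(statemap$n_states) - 1L,
             ~ which(statemap$assignment == .x) - 1L)
}

unordered_pair_grid <- function(n_states) {
  pairs <- utils::combn(seq_len(n_states) - 1L, 2)
  tibble::tibble(state_l = pairs[1, ], state_m = pairs[2, ])
}

#' Embedding-based kinetic distance between states
#'
#' For each unordered state pair \eqn{\{l, m\}} forms the interconversion
#' rate \eqn{k_{lm} = Q_l Q_{lm} + Q_m Q_{ml}} and the kinetic time
#' \eqn{t_{lm} = 1/k_{lm}}, where \eqn{Q_{lm}} comes from the embedding
#' ansatz ([embedding_transition_matrix()]) and \eqn{Q_l} is a
#' model-predicted occupancy. States span several labels while the embedding
#' is per label, so an aggregation rule is needed: `"modal"` (default)
#' represents each state by its most-occupied label and takes \eqn{Q_l} as
#' that label's occupancy; `"weighted"` uses occupancy-weighted averages of
#' \eqn{Q_{ij}} over all in-state labels and the total state occupancy for
#' \eqn{Q_l}.
#'
#' @param Q `N x N` matrix from [embedding_transition_matrix()].
#' @param label_probs length-N label occupancies of the model-generated
#'   trajectory ([label_occupancy()]).
#' @param statemap an [assign_states()] map.
#' @param aggregation `"modal"`, `"weighted"`, or `"vector"`. The `"vector"`
#'   variant represents each state by the occupancy-weighted mean of its
#'   labels' embedding vectors and applies the ansatz softmax among the
#'   state vectors themselves (requires `embedding`); `Q_l` is then the
#'   total state occupancy.
#' @param embedding `M x N` embedding matrix, needed only for
#'   `aggregation = "vector"`.
#' @return A tibble with columns `state_l`, `state_m`, `k_lm`, `t_lm`
#'   (symmetric in l, m; `t_lm = Inf`, with a warning, when the rate is 0).
#' @export
kinetic_distance <- function(Q, label_probs, statemap,
                             aggregation = c("modal", "weighted", "vector"),
                             embedding = NULL) {
  aggregation <- match.arg(aggregation)
  sets <- state_label_sets(statemap)
  if (any(lengths(sets) == 0)) abort("every state needs at least one label.")
  g <- unordered_pair_grid(statemap$n_states)
  if (aggregation == "vector") {
    if (is.null(embedding))
      abort("`embedding` is required for aggregation = \"vector\".")
    X <- vapply(sets, function(labs) {
      w <- label_probs[labs + 1L]
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
      as.numeric(embedding[, labs + 1L, drop = FALSE] %*% w)
    }, numeric(nrow(embedding)))
    Qs <- embedding_transition_matrix(X)
    Ql <- vapply(sets, function(labs) sum(label_probs[labs + 1L]), numeric(1))
    g$k_lm <- purrr::map2_dbl(g$state_l, g$state_m, function(l, m)
      Ql[l + 1] * Qs[l + 1, m + 1] + Ql[m + 1] * Qs[m + 1, l + 1])
    if (any(g$k_lm == 0)) warn("zero interconversion rate: infinite t_lm.")
    g$t_lm <- 1 / g$k_lm
    return(g)
  }
  stat <- purrr::map(sets, function(labs) {
    occ <- label_probs[labs + 1L]
    list(labs = labs, occ = occ, modal = labs[which.max(occ)],
         total = sum(occ))
  })
  qlm <- function(l, m) {
    if (aggregation == "modal") {
      Q[stat[[l + 1]]$modal + 1L, stat[[m + 1]]$modal + 1L]
    } else {
      wl <- stat[[l + 1]]$occ
      wl <- if (sum(wl) > 0) wl / sum(wl) else rep(1 / length(wl), length(wl))
      sub <- Q[stat[[l + 1]]$labs + 1L, stat[[m + 1]]$labs + 1L, drop = FALSE]
      sum(wl * rowSums(sub))
    }
  }
  ql <- function(l) {
    if (aggregation == "modal") label_probs[stat[[l + 1]]$modal + 1L]
    else stat[[l + 1]]$total
  }
  g$k_lm <- purrr::map2_dbl(g$state_l, g$state_m, function(l, m)
    ql(l) * qlm(l, m) + ql(m) * qlm(m, l))
  if (any(g$k_lm == 0)) warn("zero interconversion rate: infinite t_lm.")
  g$t_lm <- 1 / g$k_lm
  g
}

#' Counted commute time from a trajectory
#'
#' \eqn{\tau_{lm} = T / \langle N_{lm} \rangle}, where \eqn{N_{lm}} is the
#' number of committed transitions between states l and m (both directions
#' summed, as for unordered pairs), averaged over the commit-time grid, and
#' `T` is the number of analyzed samples.
#'
#' @inheritParams commit_curve
#' @return A tibble with columns `state_l`, `state_m`, `n_mean`
#'   (\eqn{\langle N_{lm}\rangle}) and `tau_lm` (`Inf`, with a warning, when
#'   no transitions were seen).
#' @export
counted_commute_time <- function(labels, statemap, commit_times = 1:200) {
  runs <- state_runs(labels, statemap)
  ns <- statemap$n_states
  g <- unordered_pair_grid(ns)
  acc <- matrix(0, nrow(g), length(commit_times))
  for (j in seq_along(commit_times)) {
    counts <- count_ordered(committed_states(runs, commit_times[j]), ns)
    both <- counts + t(counts)
    acc[, j] <- both[cbind(g$state_l + 1L, g$state_m + 1L)]
  }
  g$n_mean <- rowMeans(acc)
  if (any(g$n_mean == 0))
    warn("no transitions for some pair(s): infinite tau_lm.")
  g$tau_lm <- length(labels) / g$n_mean
  g
}

#' Min-max rescale to the unit interval
#'
#' Affine rescale mapping the smallest finite value to 0 and the largest to
#' 1; when all values are equal everything maps to 0.5 (with a warning).
#' Infinite inputs stay infinite.
#'
#' @param values numeric vector with at least 2 finite entries (or all
#'   equal).
#' @return Rescaled numeric vector.
#' @export
rescale_unit <- function(values) {
  fin <- values[is.finite(values)]
  if (length(unique(fin)) <= 1 && length(fin) == length(values)) {
    warn("all values equal: rescaled to 0.5.")
    return(rep(0.5, length(values)))
  }
  if (length(fin) < 2) abort("need at least 2 finite values to rescale.")
  (values - min(fin)) / (max(fin) - min(fin))
}

#' Side-by-side embedding and counted kinetic distances
#'
#' Convenience wrapper building the full comparison: the embedding ansatz
#' time \eqn{t_{lm}} (from the fitted model's embedding and the occupancies
#' of its generated trajectory) next to the counted commute time
#' \eqn{\tau_{lm}} (from the reference trajectory), both min-max rescaled to
#' `[0, 1]` within the table.
#'
#' @param fit a `trajlm_fit`.
#' @param reference_labels label series the commute times are counted from
#'   (typically the training data).
#' @param generated_labels model-generated label series used for the
#'   occupancies \eqn{Q_l}.
#' @param statemap an [assign_states()] map.
#' @param commit_times commit-time grid for the counted commute times.
#' @param aggregation see [kinetic_distance()].
#' @return A tibble of class `kinetic_distance_table` with columns `state_l`,
#'   `state_m`, `t_lm`, `tau_lm`, `t_rescaled`, `tau_rescaled`.
#' @export
kinetic_distance_table <- function(fit, reference_labels, generated_labels,
                                   statemap, commit_times = 1:200,
                                   aggregation = "modal") {
  Q <- embedding_transition_matrix(fit)
  occ <- label_occupancy(generated_labels, ncol(Q))
  td <- kinetic_distance(Q, occ, statemap, aggregation,
                         embedding = as_trajlm_params(fit)$embedding)
  tau <- counted_commute_time(reference_labels, statemap, commit_times)
  out <- dplyr::left_join(dplyr::select(td, "state_l", "state_m", "t_lm"),
                          dplyr::select(tau, "state_l", "state_m", "tau_lm"),
                          by = c("state_l", "state_m"))
  out$t_rescaled <- rescale_unit(out$t_lm)
  out$tau_rescaled <- rescale_unit(out$tau_lm)
  class(out) <- c("kinetic_distance_table", class(out))
  out
}
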