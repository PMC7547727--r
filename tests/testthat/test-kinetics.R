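# small two-state identity map: labels 0/1 are states 0/1
two_state_map <- function() {
  sc <- fit_scheme(c(0, 1), 2)
  assign_states(sc, c(0.25, 0.75), radius = 0.3)
}

test_that("labels map to the nearest minimum within the radius", {
  sc <- fit_scheme(c(-2.56, 2.56), 32)
  sm <- assign_states(sc, c(-2, 0, 2), radius = 0.5)
  reps <- sc$representatives
  # a representative near 0.1 belongs to the central state
  lab_01 <- which.min(abs(reps - 0.1)) - 1L
  expect_identical(sm$assignment[lab_01 + 1L], 1L)
  # 1.0 sits outside every radius
  lab_1 <- which.min(abs(reps - 1.0)) - 1L
  expect_true(is.na(sm$assignment[lab_1 + 1L]))
  # each minimum's own nearest label is assigned to it
  for (s in 1:3) {
    nearest <- which.min(abs(reps - sm$minima[s]))
    expect_identical(sm$assignment[nearest], s - 1L)
  }
  expect_error(assign_states(sc, c(0, 0), 0.5), "distinct")
  expect_error(assign_states(sc, c(-2, 2), -1), "positive")
})

test_that("state probabilities count occupancies with segment errors", {
  sm <- two_state_map()
  sp <- state_probabilities(c(0L, 0L, 1L, 1L), sm, n_segments = 2)
  expect_equal(sp$probability, c(0.5, 0.5))
  # both contiguous segments of (0,1,0,1) have identical occupancies: SE = 0
  sp01 <- state_probabilities(c(0L, 1L, 0L, 1L), sm, n_segments = 2)
  expect_equal(sp01$probability, c(0.5, 0.5))
  expect_equal(sp01$se, c(0, 0))

  set.seed(8)
  lab <- sample(0:1, 2000, replace = TRUE, prob = c(0.3, 0.7))
  sp <- state_probabilities(lab, sm, 10)
  expect_equal(sum(sp$probability), 1, tolerance = 1e-12)

  # 3-state chain with known stationary law, recovered within 3 SE
  P <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.8, 0.1,
                0.1, 0.2, 0.7), 3, byrow = TRUE)
  s3 <- sample_chain(markov_chain_spec(P, 5e4, seed = 12))
  sc3 <- fit_scheme(c(0, 2), 3)
  sm3 <- assign_states(sc3, sc3$representatives, radius = 0.2)
  sp3 <- state_probabilities(s3, sm3, 20)
  pi0 <- stationary_distribution(P)
  expect_true(all(abs(sp3$probability - pi0) <= 3 * sp3$se))
})

test_that("free energy is -log(P)/beta with flagged zeros", {
  expect_equal(free_energy(1, beta = 3), 0)
  expect_equal(free_energy(exp(-2), beta = 1), 2)
  p <- c(0.5, 0.3, 0.2)
  f1 <- free_energy(p, 9.5)
  f2 <- free_energy(p * 1e-3, 9.5)
  expect_equal(diff(f1), diff(f2), tolerance = 1e-12)
  expect_warning(fz <- free_energy(c(0.5, 0), 2), "infinite")
  expect_identical(fz[2], Inf)
  sp <- tibble::tibble(state = 0:1, probability = c(0.4, 0.6), se = 0)
  expect_equal(free_energy(sp, 1)$free_energy, -log(c(0.4, 0.6)))
})

test_that("commit counting matches the hand-enumerated worked sequence", {
  sm <- two_state_map()
  seq8 <- c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L)   # A A A B A B B B
  ct2 <- commit_transitions(seq8, sm, commit_time = 2)
  expect_equal(ct2$count[ct2$from == 0 & ct2$to == 1], 1)  # A(3) -> B(3)
  expect_equal(ct2$count[ct2$from == 1 & ct2$to == 0], 0)
  ct1 <- commit_transitions(seq8, sm, commit_time = 1)
  expect_equal(ct1$count[ct1$from == 0 & ct1$to == 1], 2)
  expect_equal(ct1$count[ct1$from == 1 & ct1$to == 0], 1)
  ct9 <- commit_transitions(seq8, sm, commit_time = 9)
  expect_true(all(ct9$count == 0))
  expect_error(commit_transitions(seq8, sm, 0), "at least 1")
})

test_that("commit counting matches an independent oracle on random chains", {
  sm <- two_state_map()
  set.seed(14)
  for (rep in 1:5) {
    lab <- sample(0:1, 300, replace = TRUE, prob = c(0.6, 0.4))
    for (ct in c(1, 2, 3, 5)) {
      got <- commit_transitions(lab, sm, ct)
      ref <- oracle_commit_counts(lab, ct, 2)
      expect_equal(got$count, ref[cbind(got$from + 1, got$to + 1)])
    }
  }
})

test_that("commit curves are non-increasing and carry segment errors", {
  # with two states there is no rerouting, so per-pair counts are monotone
  P <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  lab <- sample_chain(markov_chain_spec(P, 2e4, seed = 15))
  sm <- two_state_map()
  cc <- commit_curve(lab, sm, commit_times = 1:30, n_segments = 10)
  by_pair <- split(cc, interaction(cc$from, cc$to, drop = TRUE))
  for (df in by_pair) {
    df <- df[order(df$commit_time), ]
    expect_true(all(diff(df$count_mean) <= 1e-12))
  }

  # with three states a decommitting intermediate reroutes transitions:
  # A(5) B(3) C(5) counts A->B, B->C at commit 3 but A->C at commit 4 —
  # only the total is guaranteed non-increasing
  sc3 <- fit_scheme(c(0, 2), 3)
  sm3 <- assign_states(sc3, sc3$representatives, radius = 0.2)
  seq3 <- rep(c(0L, 1L, 2L), c(5, 3, 5))
  ct3 <- commit_transitions(seq3, sm3, 3)
  expect_equal(ct3$count[ct3$from == 0 & ct3$to == 2], 0)
  expect_equal(sum(ct3$count), 2)
  ct4 <- commit_transitions(seq3, sm3, 4)
  expect_equal(ct4$count[ct4$from == 0 & ct4$to == 2], 1)
  expect_equal(sum(ct4$count), 1)
  # commit time 1: counts equal raw transitions between assigned runs
  seg <- lab[1:2000]
  raw <- oracle_commit_counts(seg, 1, 2)
  cc1 <- commit_transitions(seg, sm, 1)
  expect_equal(cc1$count, raw[cbind(cc1$from + 1, cc1$to + 1)])

  expect_warning(cc_single <- commit_curve(lab, sm, 1:5, n_segments = 1),
                 "undefined")
  expect_true(all(is.na(cc_single$count_se)))
})

test_that("the embedding ansatz yields a row-stochastic matrix", {
  emb_same <- matrix(rep(c(1, 2), 5), nrow = 2)   # identical columns
  Q <- embedding_transition_matrix(emb_same)
  expect_equal(Q, matrix(1 / 5, 5, 5), tolerance = 1e-12)

  set.seed(16)
  emb <- matrix(rnorm(8 * 12), 8, 12)
  Q <- embedding_transition_matrix(emb)
  expect_equal(rowSums(Q), rep(1, 12), tolerance = 1e-12)
  # definition check against direct softmax of dot products
  l <- 3
  dots <- as.numeric(t(emb[, l]) %*% emb)
  expect_equal(Q[l, ], exp(dots) / sum(exp(dots)), tolerance = 1e-12)

  emb0 <- matrix(c(0, 0, 1, 0), 2)  # x0 = 0 -> all dots with x0 are 0
  Q0 <- embedding_transition_matrix(emb0)
  expect_equal(Q0[1, ], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("kinetic distance follows the interconversion-rate arithmetic", {
  sm <- two_state_map()
  Q <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  kd <- kinetic_distance(Q, c(0.5, 0.5), sm)
  expect_equal(kd$k_lm, 0.2)
  expect_equal(kd$t_lm, 5)

  # symmetry under swapping l and m: recompute with permuted states
  sc <- fit_scheme(c(0, 1), 2)
  sm_swap <- assign_states(sc, c(0.75, 0.25), radius = 0.3)
  kd_swap <- kinetic_distance(Q, c(0.5, 0.5), sm_swap)
  expect_equal(kd_swap$t_lm, kd$t_lm)

  # doubling both off-diagonal transition probabilities halves the time
  Q2 <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  kd2 <- kinetic_distance(Q2, c(0.5, 0.5), sm)
  expect_equal(kd2$t_lm, kd$t_lm / 2)

  # occupancy-weighted aggregation agrees on single-label states
  kdw <- kinetic_distance(Q, c(0.5, 0.5), sm, aggregation = "weighted")
  expect_equal(kdw$t_lm, kd$t_lm)

  # state-vector aggregation: orthogonal embeddings with |x|^2 = ln 4
  # reproduce the same 0.8/0.2 ansatz matrix, hence the same distance
  E <- diag(2) * sqrt(log(4))
  kdv <- kinetic_distance(Q, c(0.5, 0.5), sm, aggregation = "vector",
                          embedding = E)
  expect_equal(kdv$t_lm, kd$t_lm)
  expect_error(kinetic_distance(Q, c(0.5, 0.5), sm, aggregation = "vector"),
               "embedding")
})

test_that("counted commute times implement tau = T / <N>", {
  sm <- two_state_map()
  # 1000 samples alternating in blocks of 50 -> 19 committed transitions at
  # every commit time up to 50
  lab <- rep(rep(c(0L, 1L), 10), each = 50)
  tau <- counted_commute_time(lab, sm, commit_times = c(1, 10, 50))
  expect_equal(tau$n_mean, 19)
  expect_equal(tau$tau_lm, 1000 / 19)

  # adding transitions shortens the commute time
  lab2 <- rep(rep(c(0L, 1L), 20), each = 25)
  tau2 <- counted_commute_time(lab2, sm, commit_times = c(1, 10))
  expect_lt(tau2$tau_lm, tau$tau_lm)

  # no transitions -> infinite, flagged
  expect_warning(tau0 <- counted_commute_time(rep(0L, 100), sm, 1:5),
                 "no transitions")
  expect_identical(tau0$tau_lm, Inf)

  # ranking across pairs matches mean first-passage commute times of a
  # known 3-state chain
  P <- matrix(c(0.90, 0.099, 0.001,
                0.08, 0.90, 0.02,
                0.001, 0.049, 0.95), 3, byrow = TRUE)
  lab3 <- sample_chain(markov_chain_spec(P, 2e5, seed = 17))
  sc3 <- fit_scheme(c(0, 2), 3)
  sm3 <- assign_states(sc3, sc3$representatives, radius = 0.2)
  tau3 <- counted_commute_time(lab3, sm3, commit_times = 1:20)
  ref <- mfpt_commute(P)$commute
  ref_pairs <- ref[cbind(tau3$state_l + 1, tau3$state_m + 1)]
  expect_equal(order(tau3$tau_lm), order(ref_pairs))
})

test_that("unit rescaling is an order-preserving min-max map", {
  expect_equal(rescale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(18)
  v <- rnorm(10)
  r <- rescale_unit(v)
  expect_equal(order(r), order(v))
  expect_equal(range(r), c(0, 1))
  expect_equal(rescale_unit(r), r)   # idempotent on [0,1]-spanning input
  expect_warning(r5 <- rescale_unit(c(3, 3, 3)), "equal")
  expect_equal(r5, rep(0.5, 3))
})
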