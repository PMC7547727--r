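# Independent scalar-loop reference implementations used as oracles for the
# vectorized C++ kernels. Everything here is deliberately written with
# explicit elementwise loops and no shared code with the package internals.

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# one LSTM step, elementwise
oracle_lstm_step <- function(params, x, h_prev, c_prev) {
  L <- length(h_prev)
  M <- length(x)
  gate <- function(row_offset, act) {
    out <- numeric(L)
    for (k in seq_len(L)) {
      a <- params$b[row_offset + k]
      for (j in seq_len(M)) a <- a + params$W[row_offset + k, j] * x[j]
      for (j in seq_len(L)) a <- a + params$U[row_offset + k, j] * h_prev[j]
      out[k] <- act(a)
    }
    out
  }
  i <- gate(0L, oracle_sigmoid)
  f <- gate(L, oracle_sigmoid)
  g <- gate(2L * L, tanh)
  o <- gate(3L * L, oracle_sigmoid)
  cell <- numeric(L)
  h <- numeric(L)
  for (k in seq_len(L)) {
    cell[k] <- f[k] * c_prev[k] + i[k] * g[k]
    h[k] <- o[k] * tanh(cell[k])
  }
  list(h = h, cell = cell)
}

oracle_output_probs <- function(params, h) {
  N <- length(params$b_d)
  z <- numeric(N)
  for (n in seq_len(N)) {
    a <- params$b_d[n]
    for (j in seq_along(h)) a <- a + params$D[n, j] * h[j]
    z[n] <- a
  }
  e <- exp(z - max(z))
  e / sum(e)
}

# teacher-forced cross-entropy of a 0-based label sequence, scalar loop
oracle_sequence_loss <- function(params, labels) {
  L <- ncol(params$U)
  h <- numeric(L)
  cell <- numeric(L)
  total <- 0
  for (t in seq_len(length(labels) - 1)) {
    x <- params$embedding[, labels[t] + 1]
    st <- oracle_lstm_step(params, x, h, cell)
    h <- st$h
    cell <- st$cell
    p <- oracle_output_probs(params, h)
    total <- total - log(p[labels[t + 1] + 1])
  }
  total
}

# small random parameter set (seeded by the caller)
random_small_params <- function(N = 4, M = 3, L = 5, scale = 0.5) {
  structure(
    list(embedding = matrix(rnorm(M * N, sd = scale), M, N),
         W = matrix(rnorm(4 * L * M, sd = scale), 4 * L, M),
         U = matrix(rnorm(4 * L * L, sd = scale), 4 * L, L),
         b = rnorm(4 * L, sd = scale),
         D = matrix(rnorm(N * L, sd = scale), N, L),
         b_d = rnorm(N, sd = scale)),
    dims = list(n_labels = N, embed_dim = M, hidden_dim = L),
    class = "trajlm_params")
}

# direct pair counting between consecutive committed runs, written
# independently of the package's run-length machinery
oracle_commit_counts <- function(states, commit_time, n_states) {
  states <- states[!is.na(states)]
  counts <- matrix(0, n_states, n_states)
  runs_v <- integer(0)
  runs_l <- integer(0)
  for (s in states) {
    if (length(runs_v) && s == runs_v[length(runs_v)]) {
      runs_l[length(runs_l)] <- runs_l[length(runs_l)] + 1L
    } else {
      runs_v <- c(runs_v, s)
      runs_l <- c(runs_l, 1L)
    }
  }
  committed <- runs_v[runs_l >= commit_time]
  last <- NA_integer_
  for (s in committed) {
    if (!is.na(last) && s != last) counts[last + 1, s + 1] <-
        counts[last + 1, s + 1] + 1
    last <- s
  }
  counts
}
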