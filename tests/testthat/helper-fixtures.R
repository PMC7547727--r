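# Shared fixtures that are expensive to build; computed lazily, once per run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

P_STICKY <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)

# 2-state sticky-chain labels and a small model trained on them
chain_labels <- function() fixture("chain_labels", function() {
  sample_chain(markov_chain_spec(P_STICKY, length = 2e4, seed = 71))
})

chain_fit <- function() fixture("chain_fit", function() {
  train_trajlm(chain_labels(), n_labels = 2, embed_dim = 4, hidden_dim = 16,
               seq_len = 50, epochs = 25, learning_rate = 3e-3, seed = 5)
})
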