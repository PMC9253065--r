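# Shared fixtures. Expensive trained models are memoised so several tests
# (and the acceptance checks) can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# uniform 2-neighbor random walk on an n-state ring (no self transitions)
ring_transition_matrix <- function(n = 8) {
  T_mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    T_mat[i, (i %% n) + 1] <- 0.5
    T_mat[i, ((i - 2) %% n) + 1] <- 0.5
  }
  T_mat
}

# spatial exploration fit at the canonical study conditions (10x10 room,
# 10,000 pairs, full-batch Adam to the loss plateau)
trained_room_fit <- function(seed = 1) {
  memo(paste0("room_fit_", seed), function() {
    env <- build_square_room(10)
    spec <- neighborhood_spec()
    pairs <- sample_state_pairs(env, spec, n = 10000, seed = seed)
    cfg <- training_config(epochs = 1500, early_stop = TRUE, seed = seed)
    fit <- train(init_network(env$n_states, seed = seed), pairs, cfg)
    c(fit, list(env = env, spec = spec, pairs = pairs,
                T_true = environment_transition_matrix(env, spec)))
  })
}

# language fit at the canonical study conditions (5,000 pairs, 50 epochs)
trained_language_fit <- function(seed = 1) {
  memo(paste0("lang_fit_", seed), function() {
    grammar <- build_grammar()
    pairs <- sample_word_pairs(grammar, n = 5000, seed = seed)
    cfg <- training_config(epochs = 50, seed = seed)
    fit <- train(init_network(nrow(grammar$vocabulary), seed = seed),
                 pairs, cfg)
    c(fit, list(grammar = grammar, pairs = pairs,
                T_true = word_transition_matrix(grammar)))
  })
}

# a predictor network with all weights and biases zero (uniform softmax)
zero_network <- function(n_states) {
  net <- init_network(n_states, seed = 1)
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2[] <- 0
  net
}

bfs_reachable <- function(env, from, spec = neighborhood_spec(8, FALSE)) {
  seen <- rep(FALSE, env$n_states)
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, successors, env = env,
                                spec = spec)))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}
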