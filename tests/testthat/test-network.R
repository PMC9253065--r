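test_that("network layers are sized from the input and hidden fraction", {
  net <- init_network(100)
  expect_equal(c(net$n_states, net$hidden_size), c(100L, 100L))
  expect_equal(dim(net$W1), c(100, 100))
  expect_equal(dim(net$W2), c(100, 100))
  expect_equal(init_network(40)$hidden_size, 40L)
  expect_equal(init_network(100, hidden_fraction = 0.3)$hidden_size, 30L)
  expect_error(init_network(100, hidden_fraction = 0), "config error")
  expect_error(init_network(100, hidden_fraction = 3), "config error")
  expect_error(init_network(1), "config error")
  # seeded weight draw is reproducible
  expect_equal(init_network(20, seed = 5)$W1, init_network(20, seed = 5)$W1)
})

test_that("predictions are probability vectors; zero weights give uniform", {
  net <- init_network(40, seed = 3)
  p <- predict_distribution(net, 7)
  expect_length(p, 40)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_error(predict_distribution(net, 41), "out of range")

  expect_equal(predict_distribution(zero_network(25), 1), rep(1 / 25, 25))

  P <- predicted_tp_matrix(net)
  expect_equal(rowSums(P), rep(1, 40), tolerance = 1e-6)
})

test_that("a single repeated pair is memorized to accuracy 1", {
  pairs <- data.frame(input = 3L, successor = 8L)
  cfg <- training_config(epochs = 300, validation_split = 0, seed = 1)
  fit <- train(init_network(10, seed = 1), pairs, cfg)
  expect_equal(tail(fit$history$acc_train, 1), 1)
  expect_equal(which.max(predict_distribution(fit$net, 3)), 8L)
  expect_error(train(init_network(10), pairs[0, ], cfg), "training error")
})

test_that("training is deterministic given the seed", {
  g <- build_grammar()
  pairs <- sample_word_pairs(g, n = 500, seed = 4)
  cfg <- training_config(epochs = 20, seed = 4)
  f1 <- train(init_network(40, seed = 4), pairs, cfg)
  f2 <- train(init_network(40, seed = 4), pairs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$W2, f2$net$W2)
  # mini-batch path is deterministic too
  cfgb <- training_config(epochs = 5, batch_size = 64, seed = 4)
  expect_identical(train(init_network(40, seed = 4), pairs, cfgb)$history,
                   train(init_network(40, seed = 4), pairs, cfgb)$history)
})

test_that("a uniform predictor scores at chance", {
  # a guess uniform over the N outputs hits any label with probability 1/N
  room <- build_square_room(10)
  pairs <- sample_state_pairs(room, n = 1e5, seed = 6)
  set.seed(1234)  # an independent stream from the pair sampler's
  guesses <- sample.int(100, 1e5, replace = TRUE)
  acc_mc <- mean(guesses == pairs$successor)
  se <- sqrt(0.01 * 0.99 / 1e5)
  expect_lt(abs(acc_mc - 0.01), 3 * se)

  g <- build_grammar()
  wpairs <- sample_word_pairs(g, n = 1e5, seed = 6)
  set.seed(7)
  wguess <- sample.int(40, 1e5, replace = TRUE)
  acc_w <- mean(wguess == wpairs$successor)
  se_w <- sqrt(0.025 * 0.975 / 1e5)
  expect_lt(abs(acc_w - 0.025), 3 * se_w)
})

test_that("the converged spatial predictor concentrates on the neighborhood", {
  fit <- trained_room_fit(1)
  P <- predicted_tp_matrix(fit$net)
  interior <- rowcol_to_state(rep(3:8, each = 6), rep(3:8, times = 6), fit$env)
  for (s in interior[c(1, 10, 20, 36)]) {
    nb <- successors(fit$env, s, fit$spec)
    expect_gte(sum(P[s, nb]), 0.95)
  }
  # converged rows approach the transition probabilities, not a one-hot
  expect_lt(rmse(P, fit$T_true), 0.02)
  expect_lt(max(P), 0.6)
})

test_that("held-out accuracy respects the Bayes ceiling", {
  fit <- trained_room_fit(1)
  ceiling_acc <- mean(1 / vapply(which(fit$env$allowed), function(s) {
    length(successors(fit$env, s, fit$spec))
  }, numeric(1)))
  expect_equal(ceiling_acc, 0.13444, tolerance = 1e-4)
  fresh <- sample_state_pairs(fit$env, fit$spec, n = 20000, seed = 999)
  acc <- evaluate_accuracy(fit$net, fresh)
  se <- sqrt(ceiling_acc * (1 - ceiling_acc) / 20000)
  expect_lt(acc, ceiling_acc + 4 * se)
  expect_gt(acc, ceiling_acc - 4 * se)
})

test_that("rmse is a plain elementwise root-mean-square", {
  A <- matrix(1:6 / 7, 2, 3)
  expect_equal(rmse(A, A), 0)
  expect_equal(rmse(A, A + 0.1), 0.1, tolerance = 1e-12)
  expect_error(rmse(A, t(A)), "shape mismatch")
})

test_that("the architecture sweep returns one row per fraction", {
  g <- build_grammar()
  cfg <- training_config(epochs = 30, seed = 2)
  tab <- architecture_sweep(g, hidden_fractions = 1, config = cfg,
                            n_pairs = 1000)
  expect_equal(nrow(tab), 1)
  expect_named(tab, c("fraction", "hidden", "rmse", "accuracy"))

  tab2 <- architecture_sweep(g, hidden_fractions = c(0.25, 1),
                             config = cfg, n_pairs = 1000)
  expect_equal(tab2$hidden, c(10L, 40L))
  # the language task barely depends on hidden size
  expect_lt(abs(tab2$rmse[1] - tab2$rmse[2]), 0.02)
})
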