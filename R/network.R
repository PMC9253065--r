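# Three-layer feed-forward predictor: one-hot state in, ReLU hidden layer,
# softmax over all N states out. Trained with cross entropy and Adam. Because
# inputs are one-hot, the input->hidden product is a row lookup of W1, and the
# exact full-batch gradient depends on the training pairs only through their
# N x N count matrix -- both facts are exploited below.

#' Initialize a predictor network
#'
#' Layer sizes are `N` (input, one-hot states), `H = round(hidden_fraction *
#' N)` (ReLU hidden) and `N` (softmax output). Weights use fan-in-scaled
#' Gaussian (He) initialization with the given seed; biases start at zero.
#'
#' @param n_states Number of states `N` (>= 2).
#' @param hidden_fraction Hidden size as a fraction of `N`, in `(0, 2]`.
#'   Default 1 (hidden layer as large as the input).
#' @param seed Integer RNG seed for the weight draw.
#' @return An object of class `predictor_network`.
#' @export
init_network <- function(n_states, hidden_fraction = 1, seed = 1) {
  if (n_states < 2) stop("config error: need at least 2 states")
  if (hidden_fraction <= 0 || hidden_fraction > 2) {
    stop("config error: hidden_fraction must be in (0, 2]")
  }
  n <- as.integer(n_states)
  h <- max(1L, as.integer(round(hidden_fraction * n)))
  set.seed(seed)
  structure(
    list(W1 = matrix(stats::rnorm(n * h, sd = sqrt(2 / n)), n, h),
         b1 = rep(0, h),
         W2 = matrix(stats::rnorm(h * n, sd = sqrt(2 / h)), h, n),
         b2 = rep(0, n),
         n_states = n, hidden_size = h, seed = seed),
    class = "predictor_network"
  )
}

#' @export
print.predictor_network <- function(x, ...) {
  cat(sprintf("<predictor_network: %d-%d-%d (ReLU hidden, softmax output)>\n",
              x$n_states, x$hidden_size, x$n_states))
  invisible(x)
}

# forward pass for a vector of state indices; returns hidden pre/post
# activations and the softmax probabilities (rows)
.forward <- function(net, states) {
  .forward_params(net, states, net$n_states)
}

#' Predicted successor distribution of one state
#'
#' @param net A `predictor_network`.
#' @param s State index (1-based).
#' @return Length-`N` probability vector (sums to 1).
#' @export
predict_distribution <- function(net, s) {
  if (s < 1 || s > net$n_states) stop("state index out of range")
  as.vector(.forward(net, as.integer(s))$P)
}

#' Predicted transition-probability matrix
#'
#' Concatenates the network's predicted successor distributions for all
#' states into an `N` x `N` matrix; every row is a softmax output and hence
#' the matrix is always row-stochastic.
#'
#' @param net A `predictor_network`.
#' @param n_states Number of states (defaults to the network's).
#' @return `N` x `N` row-stochastic matrix.
#' @export
predicted_tp_matrix <- function(net, n_states = net$n_states) {
  stopifnot(n_states == net$n_states)
  .forward(net, seq_len(n_states))$P
}

#' Supervised training configuration
#'
#' @param epochs Number of training epochs (>= 1).
#' @param learning_rate Adam step size (> 0); default 0.01.
#' @param batch_size Pairs per update, or `NULL` (default) for full-batch
#'   training (one update per epoch on all training pairs).
#' @param validation_split Fraction of pairs held out for validation
#'   accuracy; default 0.2.
#' @param early_stop Stop once the loss has plateaued? Default `FALSE`
#'   (train for all `epochs`).
#' @param plateau_window,plateau_tol Plateau rule: stop when the loss range
#'   over the last `plateau_window` epochs falls below `plateau_tol`.
#' @param seed Integer RNG seed (data split, shuffling).
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 5000, learning_rate = 0.01,
                            batch_size = NULL, validation_split = 0.2,
                            early_stop = FALSE, plateau_window = 50,
                            plateau_tol = 1e-4, seed = 1) {
  if (epochs < 1) stop("config error: epochs must be >= 1")
  if (learning_rate <= 0) stop("config error: learning_rate must be > 0")
  if (validation_split < 0 || validation_split >= 1) {
    stop("config error: validation_split must be in [0, 1)")
  }
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 validation_split = validation_split,
                 early_stop = isTRUE(early_stop),
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol,
                 seed = as.integer(seed)),
            class = "training_config")
}

# Adam optimizer state over a named list of parameter arrays
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# pair counts as a dense N x N matrix
.pair_counts <- function(pairs, n) {
  C <- matrix(0, n, n)
  idx <- (pairs$successor - 1L) * n + pairs$input
  tab <- tabulate(idx, nbins = n * n)
  C[] <- tab
  C
}

#' Train a predictor network on state--successor pairs
#'
#' Minimizes the cross entropy between the softmax output for each input
#' state and the (one-hot) sampled successor. The optimal output for input
#' `s` is the empirical successor distribution of `s`, i.e. training
#' recovers the transition matrix row by row rather than any single one-hot
#' target. Top-1 accuracy against the stochastic sampled label is therefore
#' capped at the mean over inputs of the largest row probability (the
#' Bayes-accuracy ceiling), around 0.134 for the open 10x10 room.
#'
#' @param net A [init_network()] network.
#' @param pairs Data frame with integer columns `input`, `successor`.
#' @param config A [training_config()].
#' @return A list with elements `net` (trained network) and `history`
#'   (data frame: `epoch`, `loss`, `acc_train`, `acc_val`), plus an attribute
#'   `plateau_epoch` on `history` when early stopping triggered.
#' @export
train <- function(net, pairs, config = training_config()) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("training error: no training pairs supplied")
  }
  stopifnot(all(pairs$input >= 1), all(pairs$input <= net$n_states),
            all(pairs$successor >= 1), all(pairs$successor <= net$n_states))
  n <- net$n_states
  set.seed(config$seed)
  n_pairs <- nrow(pairs)
  n_val <- floor(config$validation_split * n_pairs)
  val_idx <- if (n_val > 0) sample.int(n_pairs, n_val) else integer(0)
  train_pairs <- if (n_val > 0) pairs[-val_idx, ] else pairs
  val_pairs <- pairs[val_idx, ]
  n_train <- nrow(train_pairs)

  C_train <- .pair_counts(train_pairs, n)
  C_val <- .pair_counts(val_pairs, n)
  Cn <- C_train / n_train
  row_w <- rowSums(Cn)

  params <- net[c("W1", "b1", "W2", "b2")]
  opt <- .adam_init(params)
  full_batch <- is.null(config$batch_size) || config$batch_size >= n_train

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc_train = numeric(0), acc_val = numeric(0))
  plateau_epoch <- NA_integer_
  loss_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    if (full_batch) {
      fw <- .forward_params(params, seq_len(n), n)
      G <- fw$P * row_w - Cn
      grads <- .backward_params(params, fw, G, seq_len(n), n)
      st <- .adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
      P_all <- fw$P
    } else {
      ord <- sample.int(n_train)
      b <- config$batch_size
      for (start in seq(1, n_train, by = b)) {
        take <- ord[start:min(start + b - 1, n_train)]
        sb <- train_pairs$input[take]
        lb <- train_pairs$successor[take]
        fw <- .forward_params(params, sb, n)
        G <- fw$P
        G[cbind(seq_along(lb), lb)] <- G[cbind(seq_along(lb), lb)] - 1
        G <- G / length(sb)
        grads <- .backward_params(params, fw, G, sb, n)
        st <- .adam_step(params, grads, opt, config$learning_rate)
        params <- st$params; opt <- st$state
      }
      P_all <- .forward_params(params, seq_len(n), n)$P
    }
    loss <- -sum(Cn * log(pmax(P_all, 1e-300)))
    pred <- max.col(P_all, ties.method = "first")
    acc_train <- sum(C_train[cbind(seq_len(n), pred)]) / n_train
    acc_val <- if (n_val > 0) {
      sum(C_val[cbind(seq_len(n), pred)]) / n_val
    } else NA_real_
    history[epoch, ] <- list(epoch, loss, acc_train, acc_val)
    loss_trace[epoch] <- loss
    if (config$early_stop && epoch >= config$plateau_window) {
      win <- loss_trace[(epoch - config$plateau_window + 1):epoch]
      if (diff(range(win)) < config$plateau_tol) {
        plateau_epoch <- epoch
        break
      }
    }
  }
  net[c("W1", "b1", "W2", "b2")] <- params
  attr(history, "plateau_epoch") <- plateau_epoch
  list(net = net, history = history)
}

# forward/backward on a raw parameter list (used inside the training loop so
# Adam-updated parameters need not be copied back into the net each step)
.forward_params <- function(params, states, n) {
  h <- length(params$b1)
  Z1 <- params$W1[states, , drop = FALSE] +
    matrix(params$b1, length(states), h, byrow = TRUE)
  A1 <- pmax(Z1, 0)
  logits <- A1 %*% params$W2 +
    matrix(params$b2, length(states), n, byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits)
  P <- P / rowSums(P)
  list(Z1 = Z1, A1 = A1, P = P)
}

.backward_params <- function(params, fw, G, states, n) {
  dW2 <- crossprod(fw$A1, G)
  db2 <- colSums(G)
  dZ1 <- (G %*% t(params$W2)) * (fw$Z1 > 0)
  db1 <- colSums(dZ1)
  dW1 <- matrix(0, n, length(params$b1))
  if (length(states) == n && all(states == seq_len(n))) {
    dW1 <- dZ1
  } else {
    agg <- rowsum(dZ1, group = states)
    dW1[as.integer(rownames(agg)), ] <- agg
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Top-1 prediction accuracy on a set of pairs
#'
#' Fraction of pairs whose sampled successor equals the argmax of the
#' network's predicted distribution for the input state.
#'
#' @param net A `predictor_network`.
#' @param pairs Data frame with `input` and `successor` columns.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(net, pairs) {
  P <- predicted_tp_matrix(net)
  pred <- max.col(P, ties.method = "first")
  mean(pred[pairs$input] == pairs$successor)
}

#' Root-mean-square error between two matrices
#'
#' `sqrt(mean((A - B)^2))` over all entries.
#'
#' @param A,B Matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
rmse <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  sqrt(mean((A - B)^2))
}

#' Hidden-layer size sweep
#'
#' Trains one network per hidden fraction on pairs sampled from a spatial
#' environment or a grammar (shared seed protocol: the same pairs and the
#' same weight-init seed across fractions) and reports the RMSE of the
#' predicted transition matrix against the analytic one together with the
#' final training accuracy.
#'
#' @param x A `grid_env` or a `grammar`.
#' @param hidden_fractions Numeric vector of hidden sizes as fractions of
#'   the input size.
#' @param config A [training_config()].
#' @param n_pairs Number of training pairs to sample.
#' @param spec Neighborhood spec (spatial environments only).
#' @return Data frame with columns `fraction`, `hidden`, `rmse`, `accuracy`.
#' @export
architecture_sweep <- function(x, hidden_fractions, config = training_config(),
                               n_pairs = 10000, spec = neighborhood_spec()) {
  stopifnot(length(hidden_fractions) >= 1)
  if (inherits(x, "grid_env")) {
    T_true <- environment_transition_matrix(x, spec)
    pairs <- sample_state_pairs(x, spec, n = n_pairs, seed = config$seed)
    n <- x$n_states
  } else if (inherits(x, "grammar")) {
    T_true <- word_transition_matrix(x)
    pairs <- sample_word_pairs(x, n = n_pairs, seed = config$seed)
    n <- nrow(x$vocabulary)
  } else {
    stop("x must be a grid_env or a grammar")
  }
  out <- lapply(hidden_fractions, function(f) {
    net <- init_network(n, hidden_fraction = f, seed = config$seed)
    fit <- train(net, pairs, config)
    data.frame(fraction = f, hidden = fit$net$hidden_size,
               rmse = rmse(predicted_tp_matrix(fit$net), T_true),
               accuracy = utils::tail(fit$history$acc_train, 1))
  })
  do.call(rbind, out)
}
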