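# Goal-directed maze navigation with a small deep Q-network: one-hot state in,
# ReLU hidden layer, one output per action. The action space is the fixed
# 9-move compass neighborhood (8 directions + stay); choosing a move into a
# wall or off the grid ends the episode with a penalty, which substitutes for
# a variable-arity action space.

.action_offsets <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 0L, 1L, -1L, 0L, 1L)
)

#' DQN agent configuration
#'
#' @param total_steps Total environment steps of training (> `warmup_steps`).
#' @param warmup_steps Initial steps with uniform-random actions filling the
#'   replay buffer before any update; default 300.
#' @param learning_rate Adam step size; default 0.001.
#' @param max_episode_steps Step cap per episode; default 30.
#' @param policy `"greedy"` (default: argmax of Q after warmup) or
#'   `"epsilon"` for epsilon-greedy.
#' @param epsilon Exploration rate when `policy = "epsilon"`.
#' @param wall_penalty Reward for choosing a wall or off-grid move (episode
#'   ends); default -1.
#' @param step_reward Per-step reward; default 0.
#' @param discount Q-learning discount; default 0.9.
#' @param hidden_fraction Hidden size as fraction of the state count.
#' @param batch_size Replay minibatch size; default 32.
#' @param replay_capacity Replay buffer size; default 2000.
#' @param target_update Steps between target-network refreshes; default 100.
#' @param seed Integer RNG seed.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(total_steps = 10000, warmup_steps = 300,
                         learning_rate = 0.001, max_episode_steps = 30,
                         policy = c("greedy", "epsilon"), epsilon = 0.05,
                         wall_penalty = -1, step_reward = 0, discount = 0.9,
                         hidden_fraction = 1, batch_size = 32,
                         replay_capacity = 2000, target_update = 100,
                         seed = 1) {
  policy <- match.arg(policy)
  if (total_steps <= warmup_steps || warmup_steps < 0) {
    stop("config error: need total_steps > warmup_steps >= 0")
  }
  if (max_episode_steps < 1) stop("config error: max_episode_steps must be >= 1")
  structure(list(total_steps = as.integer(total_steps),
                 warmup_steps = as.integer(warmup_steps),
                 learning_rate = learning_rate,
                 max_episode_steps = as.integer(max_episode_steps),
                 policy = policy, epsilon = epsilon,
                 wall_penalty = wall_penalty, step_reward = step_reward,
                 discount = discount, hidden_fraction = hidden_fraction,
                 batch_size = as.integer(batch_size),
                 replay_capacity = as.integer(replay_capacity),
                 target_update = as.integer(target_update),
                 seed = as.integer(seed)),
            class = "agent_config")
}

.q_forward <- function(params, states) {
  h <- length(params$b1)
  Z1 <- params$W1[states, , drop = FALSE] +
    matrix(params$b1, length(states), h, byrow = TRUE)
  A1 <- pmax(Z1, 0)
  Q <- A1 %*% params$W2 +
    matrix(params$b2, length(states), ncol(params$W2), byrow = TRUE)
  list(Z1 = Z1, A1 = A1, Q = Q)
}

# resulting cell of taking an action from state s: the target state index,
# or NA when the move leaves the grid
.action_target <- function(env, s, a) {
  rc <- state_to_rowcol(s, env)
  r <- rc[1, "row"] + .action_offsets[a, "dr"]
  cc <- rc[1, "col"] + .action_offsets[a, "dc"]
  if (r < 1 || r > env$height || cc < 1 || cc > env$width) return(NA_integer_)
  rowcol_to_state(r, cc, env)
}

#' Train a DQN agent to navigate toward reward cells
#'
#' Q-learning with experience replay and a periodically refreshed target
#' network. Episodes start at uniformly random allowed non-reward cells and
#' end on reaching a reward cell, on choosing a wall/off-grid move (penalty),
#' or at the step cap. During warmup actions are uniform random; afterwards
#' the configured policy (greedy by default) drives behaviour, with the
#' random episode starts providing continued exploration.
#'
#' @param env A `grid_env` with at least one nonzero reward cell.
#' @param config An [agent_config()].
#' @return List with `agent` (class `dqn_agent`) and `history` (data frame:
#'   `episode`, `reward`, `length`).
#' @export
train_agent <- function(env, config = agent_config()) {
  goal_cells <- which(env$rewards != 0)
  if (!length(goal_cells)) {
    stop("config error: environment has no reward cells")
  }
  n <- env$n_states
  h <- max(1L, as.integer(round(config$hidden_fraction * n)))
  n_act <- nrow(.action_offsets)
  set.seed(config$seed)
  params <- list(W1 = matrix(stats::rnorm(n * h, sd = sqrt(2 / n)), n, h),
                 b1 = rep(0, h),
                 W2 = matrix(stats::rnorm(h * n_act, sd = sqrt(2 / h)), h, n_act),
                 b2 = rep(0, n_act))
  target <- params
  opt <- .adam_init(params)

  cap <- config$replay_capacity
  buf <- matrix(0, cap, 5)  # s, a, r, s_next, done
  buf_n <- 0L; buf_pos <- 0L

  starts <- setdiff(which(env$allowed), goal_cells)
  # precomputed action outcome tables: next state (0 = terminal) and reward
  next_tab <- matrix(0L, n, n_act)
  rew_tab <- matrix(0, n, n_act)
  done_tab <- matrix(TRUE, n, n_act)
  for (s in which(env$allowed)) {
    for (a in seq_len(n_act)) {
      tgt <- .action_target(env, s, a)
      if (is.na(tgt) || !env$allowed[tgt]) {
        rew_tab[s, a] <- config$wall_penalty
      } else if (env$rewards[tgt] != 0) {
        rew_tab[s, a] <- env$rewards[tgt]
        next_tab[s, a] <- tgt
      } else {
        rew_tab[s, a] <- config$step_reward
        next_tab[s, a] <- tgt
        done_tab[s, a] <- FALSE
      }
    }
  }

  history <- data.frame(episode = integer(0), reward = numeric(0),
                        length = integer(0))
  ep <- 0L
  s <- starts[sample.int(length(starts), 1L)]
  ep_reward <- 0; ep_len <- 0L

  for (step in seq_len(config$total_steps)) {
    if (step <= config$warmup_steps ||
        (config$policy == "epsilon" && stats::runif(1) < config$epsilon)) {
      a <- sample.int(n_act, 1L)
    } else {
      a <- which.max(.q_forward(params, s)$Q[1, ])
    }
    r <- rew_tab[s, a]
    s_next <- next_tab[s, a]
    done <- done_tab[s, a]
    ep_reward <- ep_reward + r
    ep_len <- ep_len + 1L

    buf_pos <- buf_pos %% cap + 1L
    buf[buf_pos, ] <- c(s, a, r, if (done) s else s_next, done)
    buf_n <- min(buf_n + 1L, cap)

    if (step > config$warmup_steps) {
      take <- sample.int(buf_n, min(config$batch_size, buf_n))
      bs <- as.integer(buf[take, 1]); ba <- as.integer(buf[take, 2])
      br <- buf[take, 3]; bsn <- as.integer(buf[take, 4])
      bdone <- buf[take, 5] > 0
      qn <- .q_forward(target, bsn)$Q
      y <- br + config$discount * ifelse(bdone, 0, apply(qn, 1, max))
      fw <- .q_forward(params, bs)
      G <- matrix(0, length(take), n_act)
      sel <- cbind(seq_along(take), ba)
      G[sel] <- (fw$Q[sel] - y) / length(take)
      grads <- list(
        W1 = matrix(0, n, h), b1 = numeric(h),
        W2 = crossprod(fw$A1, G), b2 = colSums(G)
      )
      dZ1 <- (G %*% t(params$W2)) * (fw$Z1 > 0)
      grads$b1 <- colSums(dZ1)
      agg <- rowsum(dZ1, group = bs)
      grads$W1[as.integer(rownames(agg)), ] <- agg
      st <- .adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
      if (step %% config$target_update == 0L) target <- params
    }

    if (done || ep_len >= config$max_episode_steps) {
      ep <- ep + 1L
      history[ep, ] <- list(ep, ep_reward, ep_len)
      s <- starts[sample.int(length(starts), 1L)]
      ep_reward <- 0; ep_len <- 0L
    } else {
      s <- s_next
    }
  }

  agent <- structure(
    c(params, list(n_states = n, hidden_size = h, n_actions = n_act,
                   env_name = env$name, config = config)),
    class = "dqn_agent"
  )
  list(agent = agent, history = history)
}

#' @export
print.dqn_agent <- function(x, ...) {
  cat(sprintf("<dqn_agent: %d states -> %d hidden -> %d actions ('%s')>\n",
              x$n_states, x$hidden_size, x$n_actions, x$env_name))
  invisible(x)
}

#' Softmax action distribution of an agent at a state
#'
#' Softmax (temperature 1) over the Q-network's action outputs.
#'
#' @param agent A `dqn_agent`.
#' @param s Allowed state index.
#' @param env Optional `grid_env`; when supplied, wall states are rejected.
#' @return Length-9 probability vector over the compass actions.
#' @export
action_distribution <- function(agent, s, env = NULL) {
  if (s < 1 || s > agent$n_states) stop("state index out of range")
  if (!is.null(env) && !env$allowed[s]) {
    stop(sprintf("invalid state: cell %d is a wall", s))
  }
  q <- .q_forward(agent, s)$Q[1, ]
  q <- q - max(q)
  p <- exp(q)
  p / sum(p)
}

#' Extend an action distribution to a full state-probability row
#'
#' Each action's probability is placed at the cell that action reaches from
#' `s` (the stay action keeps `s`); off-grid actions have no cell and their
#' mass is dropped. With `mask = TRUE` (default) mass on wall cells is also
#' removed and the row renormalized to sum 1, keeping the resulting
#' transition matrix row-stochastic.
#'
#' @param probs Length-9 action probability vector (sums to 1).
#' @param s State the actions are taken from.
#' @param env A `grid_env`.
#' @param mask Remove wall mass and renormalize? Default `TRUE`.
#' @return Length-`N` probability row.
#' @export
extend_action_probs_to_states <- function(probs, s, env, mask = TRUE) {
  stopifnot(length(probs) == nrow(.action_offsets),
            abs(sum(probs) - 1) < 1e-6)
  row <- numeric(env$n_states)
  for (a in seq_along(probs)) {
    tgt <- .action_target(env, s, a)
    if (!is.na(tgt)) row[tgt] <- row[tgt] + probs[a]
  }
  if (mask) {
    row[!env$allowed] <- 0
    tot <- sum(row)
    if (tot > 0) row <- row / tot
  }
  row
}

#' Transition matrix implied by a trained agent's policy
#'
#' Concatenates [extend_action_probs_to_states()] rows (from
#' [action_distribution()]) over all allowed states; wall rows are zero.
#'
#' @param agent A `dqn_agent`.
#' @param env The environment the agent was trained on.
#' @param mask Passed to [extend_action_probs_to_states()].
#' @return `N` x `N` matrix, row-stochastic on allowed rows.
#' @export
policy_tp_matrix <- function(agent, env, mask = TRUE) {
  T_mat <- matrix(0, env$n_states, env$n_states)
  for (s in which(env$allowed)) {
    T_mat[s, ] <- extend_action_probs_to_states(
      action_distribution(agent, s), s, env, mask = mask)
  }
  T_mat
}

#' Ground-truth SR of the maze's uniform random walk
#'
#' The SR of [environment_transition_matrix()] restricted to allowed cells --
#' the reward-free reference against which the policy-derived SR is compared.
#'
#' @param env A `grid_env`.
#' @param spec A [neighborhood_spec()].
#' @param gamma,horizon Passed to [successor_matrix()].
#' @return A `successor_representation`.
#' @export
maze_ground_truth_sr <- function(env, spec = neighborhood_spec(),
                                 gamma = 1, horizon = 10) {
  successor_matrix(environment_transition_matrix(env, spec), gamma, horizon)
}
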