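# End-to-end pipelines tying the modules together. Each run writes its
# matrices as header-free CSV, its training history as CSV, a JSON manifest
# of configuration and metrics, and (optionally) figure panels.

#' Run the spatial exploration pipeline
#'
#' Samples state--successor pairs from an open square room, trains the
#' softmax predictor, and writes ground-truth and predicted TP and SR
#' matrices, the training history, eigenvector maps and place-field panels.
#'
#' @param out_dir Output directory (created if missing).
#' @param side Room side length; default 10 (100 states).
#' @param n_pairs Training pairs to sample; default 10000.
#' @param epochs Training epochs; default 5000.
#' @param gamma,horizon SR discount and horizon; defaults 1 and 10.
#' @param spec A [neighborhood_spec()].
#' @param seed Integer seed for sampling and training.
#' @param early_stop Stop at the loss plateau? Default `FALSE`.
#' @param write_figures Render PNG panels? Default `TRUE`.
#' @return Invisibly, a list with `net`, `history` and the `metrics` list
#'   recorded in the manifest.
#' @export
run_explore <- function(out_dir, side = 10, n_pairs = 10000, epochs = 5000,
                        gamma = 1, horizon = 10, spec = neighborhood_spec(),
                        seed = 1, early_stop = FALSE, write_figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- build_square_room(side)
  T_true <- environment_transition_matrix(env, spec)
  pairs <- sample_state_pairs(env, spec, n = n_pairs, seed = seed)
  cfg <- training_config(epochs = epochs, seed = seed,
                         early_stop = early_stop)
  fit <- train(init_network(env$n_states, seed = seed), pairs, cfg)
  T_pred <- predicted_tp_matrix(fit$net)
  sr_true <- successor_matrix(T_true, gamma, horizon)
  sr_pred <- successor_matrix(T_pred, gamma, horizon)

  write_matrix_csv(T_true, file.path(out_dir, "tp_true.csv"))
  write_matrix_csv(T_pred, file.path(out_dir, "tp_pred.csv"))
  write_matrix_csv(sr_true$M, file.path(out_dir, "sr_true.csv"))
  write_matrix_csv(sr_pred$M, file.path(out_dir, "sr_pred.csv"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  h <- fit$history
  metrics <- list(
    final_accuracy_train = utils::tail(h$acc_train, 1),
    final_accuracy_heldout = utils::tail(h$acc_val, 1),
    rmse_tp = rmse(T_pred, T_true),
    rmse_sr = rmse(sr_pred$M, sr_true$M),
    epochs_run = nrow(h),
    plateau_epoch = attr(h, "plateau_epoch")
  )
  write_manifest(file.path(out_dir, "manifest.json"), "explore",
                 list(side = side, n_pairs = n_pairs, epochs = epochs,
                      gamma = gamma, horizon = horizon,
                      connectivity = spec$connectivity,
                      include_self = spec$include_self,
                      early_stop = early_stop),
                 seed, metrics)

  if (write_figures) {
    mid <- rowcol_to_state(c((side + 1) %/% 2, 2), c((side + 1) %/% 2, 2), env)
    plot_place_fields(sr_true$M, env, mid,
                      file.path(out_dir, "sr_true_fields.png"),
                      "ground-truth SR place fields")
    plot_place_fields(sr_pred$M, env, mid,
                      file.path(out_dir, "sr_pred_fields.png"),
                      "predicted SR place fields")
    em <- eigenmaps_of_sr(sr_pred, env, k = min(30, env$n_states))
    plot_eigenmaps(em, env, file.path(out_dir, "eigenmaps.png"))
  }
  invisible(list(net = fit$net, history = h, metrics = metrics))
}

#' Run the maze navigation pipeline
#'
#' Trains the DQN agent on the corridor maze, extracts the policy transition
#' matrix and its SR, computes the reward-free random-walk SR as ground
#' truth, and writes matrices, reward history and place-field panels for
#' three sample start states.
#'
#' @param out_dir Output directory.
#' @param config An [agent_config()]; its `total_steps` must be positive.
#' @param gamma,horizon SR discount and horizon; defaults 1 and 10.
#' @param spec A [neighborhood_spec()].
#' @param seed Seed (overrides `config$seed`).
#' @param write_figures Render PNG panels? Default `TRUE`.
#' @return Invisibly, a list with `agent`, `history`, `metrics`.
#' @export
run_navigate <- function(out_dir, config = agent_config(), gamma = 1,
                         horizon = 10, spec = neighborhood_spec(), seed = 1,
                         write_figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  env <- build_alvernhe_maze()
  res <- train_agent(env, config)
  T_policy <- policy_tp_matrix(res$agent, env)
  sr_policy <- successor_matrix(T_policy, gamma, horizon)
  sr_walk <- maze_ground_truth_sr(env, spec, gamma, horizon)

  write_matrix_csv(T_policy, file.path(out_dir, "tp_policy.csv"))
  write_matrix_csv(sr_policy$M, file.path(out_dir, "sr_policy.csv"))
  write_matrix_csv(sr_walk$M, file.path(out_dir, "sr_walk.csv"))
  utils::write.csv(res$history, file.path(out_dir, "reward_history.csv"),
                   row.names = FALSE)

  h <- res$history
  k <- min(600, nrow(h))
  slope <- unname(stats::coef(stats::lm(reward ~ episode,
                                        data = h[seq_len(k), ]))[2])
  metrics <- list(
    episodes = nrow(h),
    mean_reward_first100 = mean(utils::head(h$reward, 100)),
    mean_reward_last100 = mean(utils::tail(h$reward, 100)),
    reward_slope_first600 = slope
  )
  write_manifest(file.path(out_dir, "manifest.json"), "navigate",
                 unclass(config), seed, metrics)

  if (write_figures) {
    corridor <- maze_corridor_states(env)
    starts <- corridor[round(c(0.15, 0.5, 0.85) * length(corridor))]
    plot_place_fields(sr_policy$M, env, starts,
                      file.path(out_dir, "sr_policy_fields.png"),
                      "policy SR place fields")
    plot_place_fields(sr_walk$M, env, starts,
                      file.path(out_dir, "sr_walk_fields.png"),
                      "random-walk SR place fields")
  }
  invisible(list(agent = res$agent, history = h, metrics = metrics))
}

#' Run the linguistic structure inference pipeline
#'
#' Samples word pairs from the construction grammar, trains the 40-40-40
#' softmax predictor, and writes the ground-truth and predicted TP and SR
#' (t = 2, gamma = 1) matrices, the language graph edge list, MDS embeddings
#' of TP and SR rows, and purity metrics.
#'
#' @param out_dir Output directory.
#' @param n_pairs Training pairs; default 5000.
#' @param epochs Training epochs; default 50.
#' @param batch_size Pairs per update; default `NULL` (full batch).
#' @param gamma,horizon SR parameters; defaults 1 and 2.
#' @param graph_threshold Edge cutoff for the graph export; default 1e-4.
#' @param seed Integer seed.
#' @param write_figures Render PNG panels? Default `TRUE`.
#' @return Invisibly, a list with `net`, `history`, `metrics`.
#' @export
run_language <- function(out_dir, n_pairs = 5000, epochs = 50,
                         batch_size = NULL, gamma = 1, horizon = 2,
                         graph_threshold = 1e-4, seed = 1,
                         write_figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grammar <- build_grammar()
  labels <- as.character(grammar$vocabulary$class)
  T_true <- word_transition_matrix(grammar)
  pairs <- sample_word_pairs(grammar, n = n_pairs, seed = seed)
  cfg <- training_config(epochs = epochs, batch_size = batch_size,
                         seed = seed)
  fit <- train(init_network(nrow(grammar$vocabulary), seed = seed),
               pairs, cfg)
  T_pred <- predicted_tp_matrix(fit$net)
  sr_true <- successor_matrix(T_true, gamma, horizon)
  sr_pred <- successor_matrix(T_pred, gamma, horizon)

  write_matrix_csv(T_true, file.path(out_dir, "tp_true.csv"))
  write_matrix_csv(T_pred, file.path(out_dir, "tp_pred.csv"))
  write_matrix_csv(sr_true$M, file.path(out_dir, "sr_true.csv"))
  write_matrix_csv(sr_pred$M, file.path(out_dir, "sr_pred.csv"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  export_language_graph(T_true, grammar, threshold = graph_threshold,
                        path = file.path(out_dir, "language_graph.csv"))

  # classical TP coordinates are fully deterministic; the stress refinements
  # are what separate all five classes (TP) and expose the identity-term
  # spread of the SR rows, so purity is reported on those
  emb_tp <- mds_embed(T_true, method = "classical", labels = labels)
  emb_tp_stress <- mds_embed(T_true, method = "stress", labels = labels)
  emb_sr <- mds_embed(sr_true$M, method = "stress", labels = labels)
  for (nm in c("emb_tp", "emb_tp_stress", "emb_sr")) {
    utils::write.csv(get(nm), file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }

  h <- fit$history
  metrics <- list(
    final_accuracy_train = utils::tail(h$acc_train, 1),
    final_accuracy_heldout = utils::tail(h$acc_val, 1),
    rmse_tp = rmse(T_pred, T_true),
    purity_tp = cluster_purity(emb_tp_stress, k = 5, seed = seed),
    purity_sr = cluster_purity(emb_sr, k = 5, seed = seed),
    spread_tp = within_class_spread(emb_tp_stress),
    spread_sr = within_class_spread(emb_sr)
  )
  write_manifest(file.path(out_dir, "manifest.json"), "language",
                 list(n_pairs = n_pairs, epochs = epochs,
                      batch_size = batch_size, gamma = gamma,
                      horizon = horizon, graph_threshold = graph_threshold),
                 seed, metrics)

  if (write_figures) {
    plot_embedding(emb_tp, file.path(out_dir, "mds_tp.png"),
                   "MDS of TP rows (classical)")
    plot_embedding(emb_sr, file.path(out_dir, "mds_sr.png"),
                   "MDS of SR rows (stress)")
  }
  invisible(list(net = fit$net, history = h, metrics = metrics))
}
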