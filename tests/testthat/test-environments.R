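test_that("square rooms have the right states and neighborhoods", {
  room <- build_square_room(10)
  expect_s3_class(room, "grid_env")
  expect_equal(room$n_states, 100)
  expect_true(all(room$allowed))
  expect_true(all(room$rewards == 0))
  expect_error(build_square_room(1), "invalid dimension")

  # 2x2 block: every cell is mutually adjacent under 8-connectivity
  tiny <- build_square_room(2)
  for (s in 1:4) {
    expect_length(successors(tiny, s, neighborhood_spec(8, FALSE)), 3)
  }

  # 3x3: the center sees all 8 others, corners see 3
  r3 <- build_square_room(3)
  expect_length(successors(r3, 5, neighborhood_spec(8, FALSE)), 8)
  for (s in c(1, 3, 7, 9)) {
    expect_length(successors(r3, s, neighborhood_spec(8, FALSE)), 3)
  }
})

test_that("successor counts match interior/edge/corner geometry", {
  room <- build_square_room(10)
  interior <- rowcol_to_state(5, 5, room)
  edge <- rowcol_to_state(1, 5, room)
  corner <- rowcol_to_state(1, 1, room)
  expect_length(successors(room, interior, neighborhood_spec(8, TRUE)), 9)
  expect_length(successors(room, edge, neighborhood_spec(8, FALSE)), 5)
  expect_length(successors(room, corner, neighborhood_spec(8, FALSE)), 3)
  expect_length(successors(room, interior, neighborhood_spec(4, FALSE)), 4)

  maze <- build_alvernhe_maze()
  wall <- which(!maze$allowed)[1]
  expect_error(successors(maze, wall), "wall")
})

test_that("the maze fixture has 94 connected cells and end-of-corridor rewards", {
  maze <- build_alvernhe_maze()
  expect_equal(maze$n_states, 225)
  expect_equal(sum(maze$allowed), 94)
  # every allowed cell reachable from every other (connected graph)
  reach <- bfs_reachable(maze, which(maze$allowed)[1])
  expect_setequal(reach, which(maze$allowed))
  # two food trays at the ends of the main corridor
  trays <- which(maze$rewards != 0)
  mid <- (maze$height + 1) %/% 2
  expect_setequal(trays, rowcol_to_state(c(mid, mid), c(1, maze$width), maze))
  expect_true(all(maze$rewards[trays] > 0))
  # corridor + arms partition the allowed cells
  expect_setequal(c(maze_corridor_states(maze), maze_arm_states(maze)),
                  which(maze$allowed))
})

test_that("environment fixtures survive a write/read round trip", {
  maze <- build_alvernhe_maze()
  path <- withr::local_tempfile(fileext = ".json")
  write_environment(maze, path)
  back <- read_environment(path)
  expect_equal(back$allowed, maze$allowed)
  expect_equal(back$rewards, maze$rewards)
  expect_equal(back$width, maze$width)
})

test_that("transition matrix rows are uniform over successors", {
  room <- build_square_room(10)
  spec <- neighborhood_spec()
  T_mat <- environment_transition_matrix(room, spec)
  interior <- rowcol_to_state(5, 5, room)
  expect_equal(sum(T_mat[interior, ] > 0), 9)
  expect_true(all(abs(T_mat[interior, T_mat[interior, ] > 0] - 1 / 9) < 1e-12))
  corner <- rowcol_to_state(1, 1, room)
  T_ns <- environment_transition_matrix(room, neighborhood_spec(8, FALSE))
  expect_true(all(abs(T_ns[corner, T_ns[corner, ] > 0] - 1 / 3) < 1e-12))
  expect_equal(rowSums(T_mat), rep(1, 100), tolerance = 1e-12)

  maze <- build_alvernhe_maze()
  T_mz <- environment_transition_matrix(maze, spec)
  expect_equal(unname(rowSums(T_mz)[maze$allowed]), rep(1, 94),
               tolerance = 1e-12)
  expect_true(all(rowSums(T_mz)[!maze$allowed] == 0))
  # no transition ever enters a wall
  expect_true(all(T_mz[, !maze$allowed] == 0))
})

test_that("the neighbor relation is symmetric without self-inclusion", {
  spec <- neighborhood_spec(8, FALSE)
  for (env in list(build_square_room(4), build_alvernhe_maze())) {
    for (s in which(env$allowed)) {
      for (nb in successors(env, s, spec)) {
        expect_true(s %in% successors(env, nb, spec))
      }
    }
  }
})

test_that("sampled pairs are reproducible, wall-free, and converge to T", {
  room <- build_square_room(10)
  spec <- neighborhood_spec()
  p1 <- sample_state_pairs(room, spec, n = 50, seed = 11)
  p2 <- sample_state_pairs(room, spec, n = 50, seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_state_pairs(room, spec, n = 50, seed = 12)))

  maze <- build_alvernhe_maze()
  pm <- sample_state_pairs(maze, spec, n = 2000, seed = 3)
  expect_true(all(maze$allowed[pm$input]))
  expect_true(all(maze$allowed[pm$successor]))
  expect_true(all(mapply(function(i, s) {
    s %in% successors(maze, i, spec)
  }, pm$input[1:50], pm$successor[1:50])))

  # empirical joint frequencies approach the analytic uniform-input joint
  n <- 2e5
  pr <- sample_state_pairs(room, spec, n = n, seed = 5)
  T_mat <- environment_transition_matrix(room, spec)
  joint <- T_mat / 100  # uniform input state x uniform successor
  counts <- matrix(tabulate((pr$successor - 1L) * 100 + pr$input,
                            nbins = 100 * 100), 100, 100)
  se <- sqrt(joint * (1 - joint) / n)
  dev <- abs(counts / n - joint)
  expect_lt(max((dev / pmax(se, 1e-12))[joint > 0]), 4)
  expect_true(all(counts[joint == 0] == 0))
})

test_that("sampling fails loudly when a cell has no successors", {
  # two allowed cells in opposite corners of a 3x3: isolated under
  # 4-connectivity without self
  allowed <- rep(FALSE, 9)
  allowed[c(1, 9)] <- TRUE
  env <- grid_env(3, 3, allowed = allowed)
  expect_error(sample_state_pairs(env, neighborhood_spec(4, FALSE), n = 5),
               "no successor")
})

test_that("rewards may only sit on allowed cells", {
  allowed <- rep(TRUE, 9); allowed[5] <- FALSE
  expect_error(grid_env(3, 3, allowed = allowed, rewards = c(rep(0, 4), 1, rep(0, 4))),
               "wall")
})
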