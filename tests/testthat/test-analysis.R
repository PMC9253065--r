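test_that("eigenmaps reshape sorted eigenvectors onto the lattice", {
  room <- build_square_room(10)
  sr <- successor_matrix(environment_transition_matrix(room), 1, 10)
  em <- eigenmaps_of_sr(sr, room, k = 30)
  expect_length(em$maps, 30)
  expect_true(all(vapply(em$maps, function(m) all(dim(m) == c(10, 10)),
                         logical(1))))
  expect_true(all(diff(em$values) <= 1e-9))  # descending
  em_asc <- eigenmaps_of_sr(sr, room, k = 30, order = "ascending")
  expect_true(all(diff(em_asc$values) >= -1e-9))

  expect_equal(eigenmaps_of_sr(diag(100), room, k = 100)$values, rep(1, 100))
  expect_error(eigenmaps_of_sr(matrix(0, 3, 4), room), "square")
  expect_error(eigenmaps_of_sr(sr, room, k = 101), "exceeds")

  # maze maps mask walls
  maze <- build_alvernhe_maze()
  srm <- maze_ground_truth_sr(maze)
  emm <- eigenmaps_of_sr(srm, maze, k = 5)
  wall_mask <- !state_matrix(maze$allowed, maze)
  expect_true(all(is.na(emm$maps[[1]][wall_mask])))
  expect_true(all(!is.na(emm$maps[[1]][!wall_mask])))
})

test_that("ring SR eigenvectors are discrete Fourier modes", {
  n <- 8
  T_ring <- ring_transition_matrix(n)
  M <- successor_matrix(T_ring, gamma = 0.9, horizon = Inf)$M
  e <- eigen(M)
  x <- 0:(n - 1)
  for (i in seq_len(n)) {
    v <- Re(e$vectors[, i])
    lam_T <- (1 - 1 / Re(e$values[i])) / 0.9
    k <- round(acos(pmin(1, pmax(-1, lam_T))) * n / (2 * pi))
    basis <- cbind(cos(2 * pi * k * x / n), sin(2 * pi * k * x / n))
    proj <- qr.fitted(qr(basis), v)
    cosine <- sum(v * proj) / sqrt(sum(v^2) * sum(proj^2))
    expect_gt(cosine, 0.99)
  }
})

test_that("eigenmap mesh size follows the eigenvalue rank as a strong trend", {
  room <- build_square_room(10)
  sr <- successor_matrix(environment_transition_matrix(room), 1, 10)
  em <- eigenmaps_of_sr(sr, room, k = 30)
  dom <- vapply(em$maps, dominant_spatial_frequency, numeric(1))
  # coarse-to-fine: larger eigenvalues carry lower spatial frequencies
  expect_gt(cor(seq_along(dom), dom, method = "spearman"), 0.95)
  expect_lt(dom[1], dom[30])
})

test_that("spatial frequency measures pick out planted waves", {
  x <- outer(rep(1, 16), cos(2 * pi * 3 * (0:15) / 16))
  expect_equal(dominant_spatial_frequency(x, basis = "fft"), 3)
  # half-cosine standing wave: the DCT sees it exactly, index k half-cycles
  y <- outer(cos(pi * 4 * ((0:9) + 0.5) / 10), rep(1, 10))
  expect_equal(dominant_spatial_frequency(y, basis = "dct"), 2)  # 4 half-cycles
  expect_gt(mean_spatial_frequency(y, basis = "dct"), 1.9)
})

test_that("classical MDS reproduces planar configurations exactly", {
  set.seed(21)
  X <- cbind(rnorm(12), rnorm(12), 0, 0, 0)
  emb <- mds_embed(X)
  expect_equal(as.matrix(dist(cbind(emb$x, emb$y))), as.matrix(dist(X)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(mds_embed(X[1:2, ]), "at least 3")
  expect_warning(mds_embed(matrix(1, 5, 4)), "degenerate")
})

test_that("stress refinement never exceeds the classical stress", {
  g <- build_grammar()
  M <- successor_matrix(word_transition_matrix(g), 1, 2)$M
  emb <- mds_embed(M, method = "stress",
                   labels = as.character(g$vocabulary$class))
  expect_lte(attr(emb, "stress"), attr(emb, "classical_stress"))
  expect_true(all(is.finite(emb$x)), all(is.finite(emb$y)))
})

test_that("TP-row embeddings collapse word classes to point clusters", {
  g <- build_grammar()
  labels <- as.character(g$vocabulary$class)
  T_mat <- word_transition_matrix(g)
  emb <- mds_embed(T_mat, labels = labels)
  # identical rows within a class embed at identical coordinates
  for (cl in unique(labels)) {
    pts <- as.matrix(emb[emb$label == cl, c("x", "y")])
    expect_lt(max(dist(pts)), 1e-8)
  }
  # the class rows form an orthogonal near-simplex whose double-centered
  # Gram spectrum is (1, 1, 0.606, 0.206): the top plane is degenerate and
  # projects the noun (all-zero) and pronoun rows onto the same point, so
  # the classical embedding has only 4 distinct locations (purity 35/40)
  gram_eig <- cmdscale(dist(T_mat), k = 4, eig = TRUE)$eig[1:4]
  expect_equal(gram_eig[1], gram_eig[2], tolerance = 1e-10)
  coords <- round(as.matrix(emb[, c("x", "y")]), 8)
  expect_equal(nrow(unique(coords)), 4)
  expect_equal(cluster_purity(emb, k = 5, seed = 1), 0.875)
  # the stress refinement separates all five classes while keeping the
  # within-class collapse
  emb_s <- mds_embed(T_mat, method = "stress", labels = labels)
  expect_equal(cluster_purity(emb_s, k = 5, seed = 1), 1)
  expect_lt(within_class_spread(emb_s), 1e-6)
  # the class structure of SR rows is likewise recovered once the isotropic
  # identity component is projected out (classical embedding)
  M <- successor_matrix(T_mat, 1, 2)$M
  emb_sr_c <- mds_embed(M, labels = labels)
  expect_equal(cluster_purity(emb_sr_c, k = 5, seed = 1), 1)
})

test_that("purity handles edge cases per its contract", {
  g <- build_grammar()
  emb <- mds_embed(word_transition_matrix(g),
                   labels = as.character(g$vocabulary$class))
  # k = 1: the majority class holds 10 of 40 items
  expect_equal(cluster_purity(emb, k = 1), 0.25)
  emb_same <- emb
  emb_same$label <- "only"
  expect_equal(cluster_purity(emb_same, k = 3, seed = 1), 1)
  expect_error(cluster_purity(emb, k = 41), "between 1")
})

test_that("within-class spread measures cluster density", {
  emb <- data.frame(item = 1:6,
                    x = c(0, 0, 0, 10, 11, 12), y = c(0, 1, 2, 0, 0, 0),
                    label = rep(c("a", "b"), each = 3))
  expect_gt(within_class_spread(emb), 0)
  tight <- emb; tight$x <- rep(c(0, 10), each = 3); tight$y <- 0
  expect_equal(within_class_spread(tight), 0)
})
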