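# Analyses of TP/SR matrices: eigendecomposition into grid-cell-like spatial
# maps, 2D multidimensional scaling of row vectors, and clustering purity.

#' Eigenvector maps of an SR matrix
#'
#' Eigendecomposes the SR matrix, orders the eigenpairs by the real part of
#' the eigenvalue, and reshapes the real part of each eigenvector onto the
#' environment lattice (row-major). SR matrices of random walks are generally
#' non-symmetric but similar to symmetric matrices (reversible chains), so
#' eigenvalues are real up to numerical noise; near-degenerate pairs may mix
#' within their eigenspace.
#'
#' @param sr A `successor_representation` or bare `N` x `N` matrix with
#'   `N = height * width` of `env` (wall cells included).
#' @param env The `grid_env` defining the lattice shape.
#' @param k Number of maps to keep (<= `N`).
#' @param order `"descending"` (default: largest eigenvalue, coarsest map
#'   first) or `"ascending"`.
#' @param mask_walls Set wall cells of each map to `NA`? Default `TRUE` when
#'   `env` has walls.
#' @return An object of class `eigen_maps`: list with `values` (eigenvalue
#'   real parts, in display order) and `maps` (list of `height` x `width`
#'   matrices).
#' @export
eigenmaps_of_sr <- function(sr, env, k = 30,
                            order = c("descending", "ascending"),
                            mask_walls = any(!env$allowed)) {
  order <- match.arg(order)
  M <- if (inherits(sr, "successor_representation")) sr$M else sr
  if (nrow(M) != ncol(M)) stop("SR matrix must be square")
  if (nrow(M) != env$n_states) {
    stop("SR matrix size does not match the environment lattice")
  }
  if (k > nrow(M)) stop("k exceeds the number of states")
  e <- eigen(M)
  vals <- Re(e$values)
  ord <- order(vals, decreasing = (order == "descending"))[seq_len(k)]
  maps <- lapply(ord, function(i) {
    v <- Re(e$vectors[, i])
    if (mask_walls) v[!env$allowed] <- NA_real_
    state_matrix(v, env)
  })
  structure(list(values = vals[ord], maps = maps, order = order,
                 width = env$width, height = env$height),
            class = "eigen_maps")
}

#' @export
print.eigen_maps <- function(x, ...) {
  cat(sprintf("<eigen_maps: %d maps of %d x %d, %s eigenvalues [%.3g .. %.3g]>\n",
              length(x$maps), x$height, x$width, x$order,
              x$values[1], x$values[length(x$values)]))
  invisible(x)
}

# power spectrum of a map with the matching frequency-radius grid. The DFT
# basis suits periodic domains (rings, tori); bounded rooms with reflecting
# walls host half-cosine standing waves, which the DCT-II basis resolves
# without boundary smearing (DCT index counts half-cycles per span; radii are
# halved to stay in full-cycle units).
.map_spectrum <- function(map, basis) {
  m <- map
  m[is.na(m)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  if (basis == "fft") {
    pw <- Mod(stats::fft(m))^2
    fr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    fc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  } else {
    Cr <- sapply(0:(nr - 1), function(x) cos(pi * (0:(nr - 1)) * (x + 0.5) / nr))
    Cc <- sapply(0:(nc - 1), function(x) cos(pi * (0:(nc - 1)) * (x + 0.5) / nc))
    pw <- (Cr %*% m %*% t(Cc))^2
    fr <- (0:(nr - 1)) / 2
    fc <- (0:(nc - 1)) / 2
  }
  pw[1, 1] <- 0  # drop DC
  list(power = pw, radius = sqrt(outer(fr^2, fc^2, "+")))
}

#' Spatial frequency measures of a lattice map
#'
#' `dominant_spatial_frequency` is the frequency radius (cycles per lattice
#' span) of the strongest non-DC component of the 2D power spectrum;
#' `mean_spatial_frequency` is the power-weighted average radius. Both
#' quantify the mesh size of grid-cell-like eigenmaps: finer grids have
#' higher frequency. `basis = "fft"` assumes a periodic domain (rings);
#' `basis = "dct"` resolves the half-cosine standing waves of bounded rooms.
#' `NA` cells (masked walls) are treated as zero.
#'
#' @param map A numeric matrix.
#' @param basis `"dct"` (default) or `"fft"`.
#' @return Nonnegative scalar frequency radius.
#' @export
dominant_spatial_frequency <- function(map, basis = c("dct", "fft")) {
  sp <- .map_spectrum(map, match.arg(basis))
  sp$radius[which.max(sp$power)]
}

#' @rdname dominant_spatial_frequency
#' @export
mean_spatial_frequency <- function(map, basis = c("dct", "fft")) {
  sp <- .map_spectrum(map, match.arg(basis))
  sum(sp$radius * sp$power) / sum(sp$power)
}

# Kruskal-style normalized stress of a 2D configuration against target
# distances: sqrt(sum (d - dhat)^2 / sum d^2)
.stress <- function(D, coords) {
  dhat <- stats::dist(coords)
  sqrt(sum((D - dhat)^2) / sum(D^2))
}

#' 2D embedding of row vectors by multidimensional scaling
#'
#' `method = "classical"` is the deterministic double-centered
#' eigendecomposition of squared Euclidean distances (Torgerson MDS).
#' `method = "stress"` refines the classical solution by metric SMACOF
#' majorization, which monotonically decreases the normalized stress, so the
#' final stress never exceeds the classical solution's.
#'
#' @param rows Matrix whose rows are the items to embed (>= 3 rows).
#' @param method `"classical"` (default) or `"stress"`.
#' @param labels Optional item labels (factor/character), carried into the
#'   result.
#' @param seed RNG seed (kept for interface symmetry; both methods are
#'   deterministic given the classical start).
#' @param max_iter,tol SMACOF iteration controls.
#' @return An object of class `embedding_2d`: data frame with columns
#'   `item`, `x`, `y`, `label`, and attributes `stress` and
#'   `classical_stress`.
#' @export
mds_embed <- function(rows, method = c("classical", "stress"), labels = NULL,
                      seed = 1, max_iter = 200, tol = 1e-8) {
  method <- match.arg(method)
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n < 3) stop("need at least 3 vectors to embed")
  D <- stats::dist(rows)
  if (all(D == 0)) {
    warning("degenerate embedding: all input vectors identical; ",
            "all points placed at the origin")
    coords <- matrix(0, n, 2)
  } else {
    coords <- stats::cmdscale(D, k = 2)
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  }
  classical_stress <- .stress(D, coords)
  final_stress <- classical_stress
  if (method == "stress" && any(D > 0)) {
    # metric SMACOF (Guttman transform), initialized at the classical config
    Dm <- as.matrix(D)
    X <- coords
    prev <- classical_stress
    for (it in seq_len(max_iter)) {
      dX <- as.matrix(stats::dist(X))
      B <- ifelse(dX > 0, -Dm / dX, 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
      s <- .stress(D, X)
      if (prev - s < tol) break
      prev <- s
    }
    coords <- X
    final_stress <- .stress(D, coords)
  }
  if (is.null(labels)) labels <- rep(NA_character_, n)
  item <- if (!is.null(rownames(rows))) rownames(rows) else as.character(seq_len(n))
  out <- data.frame(item = item, x = coords[, 1], y = coords[, 2],
                    label = labels)
  class(out) <- c("embedding_2d", "data.frame")
  attr(out, "stress") <- final_stress
  attr(out, "classical_stress") <- classical_stress
  out
}

#' Clustering purity of a labelled 2D embedding
#'
#' Runs multi-restart k-means on the embedding coordinates and reports the
#' fraction of items whose cluster's majority label equals their own label.
#' Majority ties break toward the lexicographically smaller label.
#'
#' @param embedding An [mds_embed()] result (or data frame with `x`, `y`,
#'   `label`).
#' @param k Number of clusters (>= 1, <= number of items).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts; default 10.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(embedding, k = 5, seed = 1, nstart = 10) {
  n <- nrow(embedding)
  if (k < 1 || k > n) stop("k must be between 1 and the number of items")
  coords <- as.matrix(embedding[, c("x", "y")])
  labels <- as.character(embedding$label)
  set.seed(seed)
  # coincident points (up to numerical noise) cannot seed distinct k-means
  # centers; when there are no more distinct locations than clusters, each
  # location is its own cluster
  scale <- max(abs(coords), .Machine$double.eps)
  key <- apply(round(coords / scale, 6), 1, paste, collapse = ",")
  cl <- if (k == 1) {
    rep(1L, n)
  } else if (length(unique(key)) <= k) {
    match(key, unique(key))
  } else {
    stats::kmeans(coords, centers = k, nstart = nstart,
                  iter.max = 50)$cluster
  }
  correct <- 0L
  for (g in unique(cl)) {
    memb <- labels[cl == g]
    tab <- table(memb)
    maj <- sort(names(tab)[tab == max(tab)])[1]
    correct <- correct + sum(memb == maj)
  }
  correct / n
}

#' Mean within-class spread of a labelled embedding
#'
#' Average over classes of the mean distance of class members to their class
#' centroid; quantifies cluster density.
#'
#' @param embedding An [mds_embed()] result.
#' @return Nonnegative scalar.
#' @export
within_class_spread <- function(embedding) {
  coords <- as.matrix(embedding[, c("x", "y")])
  labels <- as.character(embedding$label)
  mean(vapply(unique(labels), function(g) {
    pts <- coords[labels == g, , drop = FALSE]
    ctr <- colMeans(pts)
    mean(sqrt(rowSums((pts - matrix(ctr, nrow(pts), 2, byrow = TRUE))^2)))
  }, numeric(1)))
}
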