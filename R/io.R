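# Shared readers/writers: header-free delimited matrices, run manifests, and
# simple lattice heatmap figures.

#' Read / write a matrix as header-free CSV
#'
#' Matrices are exchanged as plain comma-delimited text, `N` rows by `N`
#' columns, no header and no row names.
#'
#' @param M A numeric matrix.
#' @param path File path.
#' @return `read_matrix_csv` returns a numeric matrix; `write_matrix_csv`
#'   returns `path` invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a run manifest
#'
#' JSON record of the configuration, seed, package version and metric values
#' of a pipeline run -- enough to reproduce the run's deterministic stages.
#'
#' @param path Output file.
#' @param task Task name.
#' @param config Configuration list (echoed verbatim).
#' @param seed Integer seed of the run.
#' @param metrics Named list of scalar metrics.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, task, config, seed, metrics) {
  jsonlite::write_json(
    list(task = task,
         package = "cogmapsr",
         version = as.character(utils::packageVersion("cogmapsr")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         config = config,
         metrics = metrics),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

# heatmap of a per-state vector (or lattice matrix) on the environment grid;
# walls rendered blank
.plot_state_map <- function(v, env, main = "", mark = NULL) {
  m <- if (is.matrix(v)) v else state_matrix(v, env)
  m[!state_matrix(env$allowed, env)] <- NA
  # image() draws row 1 at the bottom; flip so row 1 is the top of the room
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(seq_len(env$width), seq_len(env$height), z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  useRaster = FALSE)
  if (!is.null(mark)) {
    rc <- state_to_rowcol(mark, env)
    graphics::points(rc[, "col"], env$height + 1 - rc[, "row"],
                     pch = 0, cex = 1.6, col = "green3", lwd = 2)
  }
  invisible(NULL)
}

#' Render a panel of SR place fields
#'
#' One heatmap per start state: row `s` of the SR matrix reshaped onto the
#' environment (the model place-cell firing field of `s`).
#'
#' @param M SR (or TP) matrix.
#' @param env The environment.
#' @param states Start states to render.
#' @param path PNG output path.
#' @param main Overall title.
#' @return `path`, invisibly.
#' @export
plot_place_fields <- function(M, env, states, path, main = "SR place fields") {
  grDevices::png(path, width = 320 * length(states), height = 340)
  op <- graphics::par(mfrow = c(1, length(states)), mar = c(1, 1, 3, 1),
                      oma = c(0, 0, 2, 0))
  on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
  for (s in states) {
    .plot_state_map(M[s, ], env, main = sprintf("state %d", s), mark = s)
  }
  graphics::mtext(main, outer = TRUE)
  invisible(path)
}

#' Render a grid of eigenvector maps
#'
#' @param em An [eigenmaps_of_sr()] result.
#' @param env The environment.
#' @param path PNG output path.
#' @param ncol Panels per row.
#' @return `path`, invisibly.
#' @export
plot_eigenmaps <- function(em, env, path, ncol = 6) {
  k <- length(em$maps)
  nrow_p <- ceiling(k / ncol)
  grDevices::png(path, width = 170 * ncol, height = 180 * nrow_p)
  op <- graphics::par(mfrow = c(nrow_p, ncol), mar = c(0.5, 0.5, 2, 0.5))
  on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
  for (i in seq_len(k)) {
    .plot_state_map(em$maps[[i]], env,
                    main = sprintf("#%d  λ=%.2f", i, em$values[i]))
  }
  invisible(path)
}

#' Scatter plot of a labelled 2D embedding
#'
#' @param embedding An [mds_embed()] result.
#' @param path PNG output path.
#' @param main Title.
#' @return `path`, invisibly.
#' @export
plot_embedding <- function(embedding, path, main = "MDS embedding") {
  grDevices::png(path, width = 560, height = 520)
  on.exit(grDevices::dev.off(), add = TRUE)
  lab <- factor(embedding$label)
  graphics::plot(embedding$x, embedding$y, col = as.integer(lab), pch = 19,
                 xlab = "dimension 1", ylab = "dimension 2", main = main)
  graphics::legend("topright", legend = levels(lab),
                   col = seq_len(nlevels(lab)), pch = 19, cex = 0.8)
  invisible(path)
}
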