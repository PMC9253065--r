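# Discrete grid-like state spaces: an open square room and a corridor maze
# with side arms. States are cells of the full width x height lattice in
# row-major order (state 1 is the top-left cell), so that length-N vectors
# reshape directly onto the room, walls included.

#' Construct a grid environment
#'
#' Low-level constructor for a discrete 2D state space. Every cell of the
#' `width` x `height` lattice is a state; `allowed` marks traversable cells
#' (walls/barriers are `FALSE`). Rewards may only sit on allowed cells.
#'
#' @param width,height Lattice dimensions in cells (each >= 2).
#' @param allowed Logical vector of length `width * height` in row-major
#'   order, or `NULL` for all-allowed.
#' @param rewards Numeric vector of per-cell rewards (row-major), or `NULL`
#'   for none.
#' @param name Optional environment name.
#' @return An object of class `grid_env` with fields `width`, `height`,
#'   `n_states`, `allowed`, `rewards`, `name`.
#' @export
grid_env <- function(width, height, allowed = NULL, rewards = NULL,
                     name = "grid") {
  if (width < 2 || height < 2) {
    stop("invalid dimension: width and height must both be >= 2")
  }
  n <- as.integer(width * height)
  if (is.null(allowed)) allowed <- rep(TRUE, n)
  if (is.null(rewards)) rewards <- rep(0, n)
  allowed <- as.logical(allowed)
  rewards <- as.numeric(rewards)
  stopifnot(length(allowed) == n, length(rewards) == n)
  if (!any(allowed)) stop("environment must have at least one allowed cell")
  if (any(rewards[!allowed] != 0)) {
    stop("rewards must be zero on wall cells")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_states = n, allowed = allowed, rewards = rewards, name = name),
    class = "grid_env"
  )
}

#' @export
print.grid_env <- function(x, ...) {
  cat(sprintf("<grid_env '%s': %d x %d, %d/%d allowed, %d reward cell(s)>\n",
              x$name, x$height, x$width, sum(x$allowed), x$n_states,
              sum(x$rewards != 0)))
  invisible(x)
}

#' Convert between flat state indices and (row, col) coordinates
#'
#' States are 1-based, row-major over the full lattice:
#' `s = (row - 1) * width + col`.
#'
#' @param s Integer state indices.
#' @param env A `grid_env`.
#' @return `state_to_rowcol`: a two-column matrix of (row, col);
#'   `rowcol_to_state`: integer state indices.
#' @export
state_to_rowcol <- function(s, env) {
  cbind(row = (s - 1L) %/% env$width + 1L,
        col = (s - 1L) %% env$width + 1L)
}

#' @rdname state_to_rowcol
#' @param row,col 1-based lattice coordinates.
#' @export
rowcol_to_state <- function(row, col, env) {
  as.integer((row - 1L) * env$width + col)
}

#' Reshape a per-state vector onto the environment lattice
#'
#' @param v Numeric vector of length `env$n_states` (row-major state order).
#' @param env A `grid_env`.
#' @return A `height` x `width` matrix.
#' @export
state_matrix <- function(v, env) {
  stopifnot(length(v) == env$n_states)
  matrix(v, nrow = env$height, ncol = env$width, byrow = TRUE)
}

#' Neighborhood specification
#'
#' Defines which cells count as direct successors of a state: 4- or
#' 8-connectivity, with or without the state itself. The default (8-connected
#' including self) gives interior cells of an open room 9 successor states.
#'
#' @param connectivity 4 or 8 (default 8).
#' @param include_self Should a state count among its own successors?
#'   Default `TRUE`.
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(connectivity = 8, include_self = TRUE) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(connectivity = as.integer(connectivity),
                 include_self = isTRUE(include_self)),
            class = "neighborhood_spec")
}

#' Build an open square room
#'
#' An obstacle-free `side` x `side` room in which every cell is an allowed
#' state; the canonical exploration environment has `side = 10`, i.e. 100
#' states.
#'
#' @param side Side length in cells (>= 2).
#' @return A `grid_env` with all cells allowed and no rewards.
#' @export
build_square_room <- function(side = 10) {
  if (side < 2) stop("invalid dimension: side must be >= 2")
  grid_env(side, side, name = sprintf("square%d", side))
}

#' Direct successor states of a cell
#'
#' Successors are the allowed cells adjacent to `s` under the neighborhood
#' spec; walls and off-grid positions are never successors.
#'
#' @param env A `grid_env`.
#' @param s An allowed state index.
#' @param spec A [neighborhood_spec()].
#' @return Sorted integer vector of successor state indices.
#' @export
successors <- function(env, s, spec = neighborhood_spec()) {
  if (s < 1 || s > env$n_states) stop("state index out of range")
  if (!env$allowed[s]) stop(sprintf("invalid state: cell %d is a wall", s))
  rc <- state_to_rowcol(s, env)
  off <- if (spec$connectivity == 8L) {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))
  }
  r <- rc[1, "row"] + off[, "dr"]
  cc <- rc[1, "col"] + off[, "dc"]
  keep <- r >= 1L & r <= env$height & cc >= 1L & cc <= env$width
  nb <- rowcol_to_state(r[keep], cc[keep], env)
  nb <- nb[env$allowed[nb]]
  if (spec$include_self) nb <- c(nb, s)
  sort(unique(as.integer(nb)))
}

#' Ground-truth transition matrix of the uniform random walk
#'
#' Row `s` is uniform over `successors(env, s, spec)`; rows of wall cells are
#' all zero, as are all columns entries pointing into walls.
#'
#' @inheritParams successors
#' @return An `N` x `N` row-stochastic matrix (wall rows sum to 0).
#' @export
environment_transition_matrix <- function(env, spec = neighborhood_spec()) {
  n <- env$n_states
  T_mat <- matrix(0, n, n)
  for (s in which(env$allowed)) {
    nb <- successors(env, s, spec)
    if (length(nb)) T_mat[s, nb] <- 1 / length(nb)
  }
  T_mat
}

#' Sample state--successor training pairs
#'
#' Draws `n` pairs by choosing an input state uniformly among allowed cells
#' (walls are excluded as inputs) and then a successor uniformly among the
#' input's direct successor states.
#'
#' @inheritParams successors
#' @param n Number of pairs (>= 1).
#' @param seed Integer RNG seed.
#' @return A data frame with integer columns `input` and `successor`.
#' @export
sample_state_pairs <- function(env, spec = neighborhood_spec(), n = 10000,
                               seed = 1) {
  stopifnot(n >= 1)
  alw <- which(env$allowed)
  succ <- lapply(alw, function(s) successors(env, s, spec))
  bad <- alw[lengths(succ) == 0]
  if (length(bad)) {
    stop(sprintf("sampling error: cell %d has no successor states", bad[1]))
  }
  set.seed(seed)
  inputs <- alw[sample.int(length(alw), n, replace = TRUE)]
  key <- match(inputs, alw)
  successors_drawn <- vapply(key, function(k) {
    nb <- succ[[k]]
    nb[sample.int(length(nb), 1L)]
  }, integer(1))
  data.frame(input = inputs, successor = successors_drawn)
}

# ---- fixture serialization --------------------------------------------------

#' Read / write grid environments as JSON text fixtures
#'
#' The fixture format stores `width`, `height`, `rows` (strings of `#` for
#' walls and `.` for allowed cells, top row first) and a `rewards` list of
#' `{row, col, value}` records (1-based coordinates).
#'
#' @param path File path.
#' @return `read_environment` returns a `grid_env`.
#' @export
read_environment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- j$rows
  stopifnot(length(rows) == j$height, all(nchar(rows) == j$width))
  allowed <- unlist(lapply(rows, function(r) {
    strsplit(r, "")[[1]] == "."
  }), use.names = FALSE)
  env <- grid_env(j$width, j$height, allowed = allowed,
                  name = if (!is.null(j$name)) j$name else "fixture")
  if (!is.null(j$rewards) && length(j$rewards)) {
    rw <- as.data.frame(j$rewards)
    s <- rowcol_to_state(rw$row, rw$col, env)
    env$rewards[s] <- rw$value
    if (any(env$rewards[!env$allowed] != 0)) {
      stop("fixture places rewards on wall cells")
    }
  }
  env
}

#' @rdname read_environment
#' @param env A `grid_env` to serialize.
#' @export
write_environment <- function(env, path) {
  am <- state_matrix(as.numeric(env$allowed), env)
  rows <- apply(am, 1, function(r) paste(ifelse(r > 0, ".", "#"),
                                         collapse = ""))
  rs <- which(env$rewards != 0)
  rewards <- if (length(rs)) {
    rc <- state_to_rowcol(rs, env)
    data.frame(row = rc[, "row"], col = rc[, "col"],
               value = env$rewards[rs])
  } else {
    list()
  }
  jsonlite::write_json(
    list(name = env$name, width = env$width, height = env$height,
         rows = rows, rewards = rewards),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' The corridor maze with side-arm detours
#'
#' A 15 x 15 lattice of which exactly 94 cells are traversable: a full-width
#' main corridor along the middle row, seven 6-cell arms branching up (one
#' reaching the top edge) and six branching down, and a food-tray reward of
#' +10 at each end of the corridor. The topology emulates the classic rodent
#' detour maze: side arms are dead-end detours off the rewarded corridor.
#'
#' @return A `grid_env` with 225 cells, 94 allowed, 2 reward cells.
#' @export
build_alvernhe_maze <- function() {
  path <- system.file("extdata", "alvernhe_maze.json", package = "cogmapsr")
  if (path == "") path <- file.path("inst", "extdata", "alvernhe_maze.json")
  read_environment(path)
}

#' Cells belonging to the maze's main corridor / side arms
#'
#' Helpers used by the detour-suppression analysis: the main corridor is the
#' middle lattice row; side arms are every other allowed cell.
#'
#' @param env The maze environment.
#' @return Integer state indices.
#' @export
maze_corridor_states <- function(env) {
  mid <- (env$height + 1L) %/% 2L
  s <- rowcol_to_state(rep(mid, env$width), seq_len(env$width), env)
  s[env$allowed[s]]
}

#' @rdname maze_corridor_states
#' @export
maze_arm_states <- function(env) {
  setdiff(which(env$allowed), maze_corridor_states(env))
}
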