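# Exact successor-representation mathematics. The SR of a transition matrix T
# at discount gamma and horizon h is M = sum_{t=0}^{h} gamma^t T^t (the t = 0
# identity term included); the infinite-horizon SR with gamma < 1 is the
# closed form (I - gamma T)^{-1}.

#' Successor representation of a transition matrix
#'
#' Computes the discounted expected-occupancy matrix
#' `M = sum_{t=0}^{horizon} gamma^t T^t`. Finite horizons are evaluated by
#' Horner's scheme `I + gamma T (I + gamma T (...))`; `horizon = Inf`
#' requires `gamma < 1` and uses the closed form `solve(I - gamma T)`.
#' All-zero rows of `T` (walls, terminal words) propagate naturally: no
#' renormalization is applied.
#'
#' @param T_mat Square transition matrix (rows sum to 1 or 0).
#' @param gamma Discount factor in `[0, 1]`.
#' @param horizon Nonnegative integer, or `Inf`.
#' @return An object of class `successor_representation`: a list with the
#'   matrix `M` and the `gamma` and `horizon` used.
#' @export
successor_matrix <- function(T_mat, gamma = 1, horizon = 10) {
  stopifnot(is.matrix(T_mat), nrow(T_mat) == ncol(T_mat),
            gamma >= 0, gamma <= 1, horizon >= 0)
  n <- nrow(T_mat)
  I <- diag(n)
  if (is.infinite(horizon)) {
    if (gamma >= 1) {
      stop("divergence: infinite horizon requires gamma < 1")
    }
    M <- solve(I - gamma * T_mat)
  } else if (gamma == 0 || horizon == 0) {
    M <- I
  } else {
    # Horner: M_h = I + gamma T M_{h-1}
    M <- I
    for (t in seq_len(horizon)) M <- I + gamma * (T_mat %*% M)
  }
  structure(list(M = M, gamma = gamma, horizon = horizon),
            class = "successor_representation")
}

#' @export
print.successor_representation <- function(x, ...) {
  cat(sprintf("<successor_representation: %d x %d, gamma = %g, horizon = %s>\n",
              nrow(x$M), ncol(x$M), x$gamma, format(x$horizon)))
  invisible(x)
}

#' Value function from an SR matrix and a reward vector
#'
#' `V = M R`: the expected discounted reward from each state. With `R = 1`
#' everywhere this is the total discounted occupancy (row sums of `M`).
#'
#' @param sr A `successor_representation` (or a bare SR matrix).
#' @param R Reward vector of length `N`.
#' @return Numeric vector `V` of length `N`.
#' @export
value_function <- function(sr, R) {
  M <- if (inherits(sr, "successor_representation")) sr$M else sr
  if (length(R) != nrow(M)) {
    stop(sprintf("dimension error: reward vector has length %d, need %d",
                 length(R), nrow(M)))
  }
  as.vector(M %*% R)
}

#' Brute-force partial-sum SR reference
#'
#' Literal term-by-term accumulation of `gamma^t T^t` by repeated matrix
#' multiplication. Kept as an independent code path from
#' [successor_matrix()]'s Horner/closed-form evaluation; intended for
#' cross-checks.
#'
#' @inheritParams successor_matrix
#' @return The SR as a bare matrix.
#' @export
sr_partial_sum_oracle <- function(T_mat, gamma = 1, horizon = 10) {
  stopifnot(is.finite(horizon), horizon >= 0)
  n <- nrow(T_mat)
  acc <- diag(n)
  Tt <- diag(n)
  if (horizon >= 1) {
    for (t in seq_len(horizon)) {
      Tt <- Tt %*% T_mat
      acc <- acc + gamma^t * Tt
    }
  }
  acc
}
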