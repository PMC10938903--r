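# Walker-ensemble simulation.
#
# An ensemble is a W x N logical matrix: each row is one independent network
# instance ("walker").  Synchronous update recomputes every node of every
# walker from the pre-step state; asynchronous update recomputes exactly one
# uniformly chosen node per walker per step.  All randomness flows from
# per-step seeds derived from one master seed, so a schedule replayed with the
# same seed yields the identical node-index sequence regardless of batching.

# Derived seeds: splitmix-style integer hash kept in [0, 2^31).
derive_seed <- function(seed, stream = 0L, step = 0L) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + stream * 69621 + step * 16807
  as.integer(x %% 2147483647)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Create an update schedule
#'
#' @param scheme `"synchronous"` (all nodes every step, deterministic) or
#'   `"asynchronous"` (one uniformly random node per walker per step)
#' @param seed integer master seed; mandatory for asynchronous schedules so
#'   that no stochastic run is silently irreproducible
#' @return an `update_schedule` object
#' @export
update_schedule <- function(scheme = c("synchronous", "asynchronous"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "asynchronous" && is.null(seed)) {
    stop("asynchronous schedules require a seed", call. = FALSE)
  }
  structure(
    list(scheme = scheme, seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "update_schedule"
  )
}

# Node indices updated at step t (1-based), one per walker.
schedule_indices <- function(schedule, N, W, t) {
  with_seed(
    derive_seed(schedule$seed, stream = 1L, step = t),
    sample.int(N, W, replace = TRUE)
  )
}

#' Sample uniformly random initial walker states
#'
#' @param N node count
#' @param W walker count
#' @param seed integer seed
#' @return `walker_ensemble`: list with `states` (W x N logical matrix) and
#'   step counter `t = 0`
#' @export
sample_initial_states <- function(N, W, seed) {
  stopifnot(N >= 1L, W >= 1L)
  states <- with_seed(
    derive_seed(seed, stream = 2L),
    matrix(sample(c(FALSE, TRUE), N * W, replace = TRUE), nrow = W, ncol = N)
  )
  walker_ensemble(states)
}

#' Wrap a binary state matrix as a walker ensemble
#'
#' @param states W x N matrix of 0/1 or logical values; columns follow the
#'   network's node order
#' @param t step counter (default 0)
#' @return a `walker_ensemble`
#' @export
walker_ensemble <- function(states, t = 0L) {
  states <- as.matrix(states)
  mode(states) <- "logical"
  if (anyNA(states)) stop("states must be 0/1", call. = FALSE)
  structure(list(states = states, t = as.integer(t)), class = "walker_ensemble")
}

state_cols <- function(X) {
  lapply(seq_len(ncol(X)), function(j) X[, j])
}

# One synchronous sweep of a raw logical matrix.
sync_step_matrix <- function(X, net) {
  env <- list(.s = state_cols(X))
  new <- X
  for (j in seq_len(net$N)) {
    v <- eval(net$exprs[[j]], env)
    new[, j] <- v
  }
  new
}

# One asynchronous step (indices idx, one node per walker) of a raw matrix.
async_step_matrix <- function(X, net, idx) {
  env <- list(.s = state_cols(X))
  for (j in unique(idx)) {
    v <- eval(net$exprs[[j]], env)
    sel <- idx == j
    X[sel, j] <- if (length(v) == 1L) v else v[sel]
  }
  X
}

#' Advance a walker ensemble by one step
#'
#' @param ensemble a [walker_ensemble()]
#' @param net a [boolean_network()]
#' @param schedule an [update_schedule()]
#' @return the advanced ensemble (step counter incremented)
#' @examples
#' net <- parse_network("A, !B\nB, !A")
#' e <- walker_ensemble(matrix(c(0, 0), nrow = 1))
#' step(e, net, update_schedule("synchronous"))$states
#' @export
step <- function(ensemble, net, schedule) {
  stopifnot(
    inherits(ensemble, "walker_ensemble"),
    inherits(net, "boolean_network"),
    inherits(schedule, "update_schedule")
  )
  X <- ensemble$states
  if (ncol(X) != net$N) stop("ensemble has wrong column count", call. = FALSE)
  t_next <- ensemble$t + 1L
  X <- if (schedule$scheme == "synchronous") {
    sync_step_matrix(X, net)
  } else {
    async_step_matrix(X, net, schedule_indices(schedule, net$N, nrow(X), t_next))
  }
  walker_ensemble(X, t_next)
}

# Default simulation length: 55 N + 6000 total steps, with the averaging
# window the largest multiple of 4 not exceeding half the total.
default_window <- function(N) {
  total <- 55L * N + 6000L
  T_w <- 4L * (total %/% 2L %/% 4L)
  list(T_b = total - T_w, T_w = T_w)
}

#' Evolve an ensemble and take windowed time averages
#'
#' Runs `T_b` burn-in steps followed by `T_w` averaging steps and returns the
#' per-walker window mean of every node together with ensemble-aggregated
#' means over the four equal quarters of the window (the convergence
#' diagnostic).
#'
#' @param net a [boolean_network()]
#' @param ensemble a [walker_ensemble()] of initial states
#' @param schedule an [update_schedule()]
#' @param T_b burn-in steps (>= 0)
#' @param T_w window steps; must be a positive multiple of 4
#' @return a `window_average`: list with `means` (W x N matrix of window
#'   means), `quarters` (4 x N ensemble-mean matrix), `T_b`, `T_w`, and the
#'   final `states`
#' @export
run_with_window <- function(net, ensemble, schedule, T_b = NULL, T_w = NULL) {
  stopifnot(inherits(ensemble, "walker_ensemble"))
  if (is.null(T_b) || is.null(T_w)) {
    dw <- default_window(net$N)
    if (is.null(T_b)) T_b <- dw$T_b
    if (is.null(T_w)) T_w <- dw$T_w
  }
  if (T_w < 4L || T_w %% 4L != 0L) {
    stop("T_w must be a multiple of 4 and at least 4", call. = FALSE)
  }
  X <- ensemble$states
  W <- nrow(X)
  N <- net$N
  asyn <- schedule$scheme == "asynchronous"
  for (t in seq_len(T_b)) {
    X <- if (asyn) {
      async_step_matrix(X, net, schedule_indices(schedule, N, W, t))
    } else {
      sync_step_matrix(X, net)
    }
  }
  S <- matrix(0, W, N)
  quarters <- matrix(0, 4L, N, dimnames = list(NULL, net$nodes))
  q_len <- T_w %/% 4L
  for (t in seq_len(T_w)) {
    X <- if (asyn) {
      async_step_matrix(X, net, schedule_indices(schedule, N, W, T_b + t))
    } else {
      sync_step_matrix(X, net)
    }
    S <- S + X
    qi <- 1L + (t - 1L) %/% q_len
    quarters[qi, ] <- quarters[qi, ] + colMeans(X)
  }
  structure(
    list(
      means = structure(S / T_w, dimnames = list(NULL, net$nodes)),
      quarters = quarters / q_len,
      T_b = T_b, T_w = T_w,
      states = X
    ),
    class = "window_average"
  )
}

#' Check window convergence from quarter-mean disagreement
#'
#' The diagnostic is the largest, over nodes, of the spread (max minus min) of
#' the four ensemble-aggregated quarter means of the averaging window.
#'
#' @param avg a `window_average` from [run_with_window()]
#' @param tol acceptance threshold; the default is the worst-case disagreement
#'   the simulation protocol is calibrated to (0.0066)
#' @return list with `converged` (logical) and `worst` (the max disagreement)
#' @export
convergence_check <- function(avg, tol = 0.0066) {
  stopifnot(inherits(avg, "window_average"))
  spread <- apply(avg$quarters, 2L, function(x) max(x) - min(x))
  worst <- max(spread)
  list(converged = worst <= tol, worst = worst)
}

# ---- Paired (perturbed/unperturbed) trajectories ----------------------------

#' Run matched perturbed/unperturbed trajectory pairs on one shared schedule
#'
#' Each walker row of `X0` is paired with a copy whose `target` column is
#' flipped at t = 0.  Both members of every pair update the same node set at
#' every step (essential under stochastic update).  Over the averaging window
#' the per-step Hamming distance and both members' per-node means are
#' accumulated.
#'
#' @param net a [boolean_network()]
#' @param X0 W x N logical matrix of unperturbed initial states
#' @param target column index of the initially flipped node
#' @param schedule an [update_schedule()]
#' @param T_b,T_w burn-in and window lengths (window a multiple of 4)
#' @return list with `hamming` (per-pair window-mean Hamming distance, length
#'   W), `mean_x` and `mean_y` (W x N window-mean matrices for the
#'   unperturbed and perturbed members)
#' @export
run_pair_window <- function(net, X0, target, schedule, T_b, T_w) {
  if (T_w < 4L || T_w %% 4L != 0L) {
    stop("T_w must be a multiple of 4 and at least 4", call. = FALSE)
  }
  X <- X0
  Y <- X0
  Y[, target] <- !Y[, target]
  W <- nrow(X)
  N <- net$N
  asyn <- schedule$scheme == "asynchronous"
  for (t in seq_len(T_b)) {
    if (asyn) {
      idx <- schedule_indices(schedule, N, W, t)
      X <- async_step_matrix(X, net, idx)
      Y <- async_step_matrix(Y, net, idx)
    } else {
      X <- sync_step_matrix(X, net)
      Y <- sync_step_matrix(Y, net)
    }
  }
  hsum <- numeric(W)
  SX <- matrix(0, W, N)
  SY <- matrix(0, W, N)
  for (t in seq_len(T_w)) {
    if (asyn) {
      idx <- schedule_indices(schedule, N, W, T_b + t)
      X <- async_step_matrix(X, net, idx)
      Y <- async_step_matrix(Y, net, idx)
    } else {
      X <- sync_step_matrix(X, net)
      Y <- sync_step_matrix(Y, net)
    }
    hsum <- hsum + rowSums(X != Y)
    SX <- SX + X
    SY <- SY + Y
  }
  list(hamming = hsum / T_w, mean_x = SX / T_w, mean_y = SY / T_w)
}

#' Export per-walker window means as a data frame
#'
#' @param avg a `window_average`
#' @return data frame with columns `walker`, `node`, `window_mean`
#' @export
window_means_df <- function(avg) {
  stopifnot(inherits(avg, "window_average"))
  W <- nrow(avg$means)
  nodes <- colnames(avg$means)
  data.frame(
    walker = rep(seq_len(W), times = length(nodes)),
    node = rep(nodes, each = W),
    window_mean = as.vector(avg$means)
  )
}
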