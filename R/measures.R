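# Perturbation-response measures.
#
# All four measures average a per-pair quantity over matched
# perturbed/unperturbed trajectory pairs and over perturbation targets:
#   derrida        mean Hamming distance after one network update
#                  (1 synchronous step, or N asynchronous steps)
#   final_hamming  window time-average of the per-step Hamming distance
#   fragility      L1 distance between the two members' window-mean vectors
#   quasicoherence fraction of pairs whose quasiattractor signatures agree
# Source-handling modes: "p" perturbs any node; "f" excludes source nodes
# from the flip-target set and from the averaging prefactor, while the
# Hamming/L1 norms still run over all nodes (source coordinates of a pair
# agree by construction in mode f).

measure_result <- function(measure, scheme, source_mode, value, stderr,
                           W, T_b = NA_integer_, T_w = NA_integer_, seed,
                           extra = list()) {
  structure(
    c(
      list(
        measure = measure, scheme = scheme, source_mode = source_mode,
        value = value, stderr = stderr,
        W = W, T_b = T_b, T_w = T_w, seed = seed
      ),
      extra
    ),
    class = "measure_result"
  )
}

#' @export
print.measure_result <- function(x, ...) {
  sub <- paste0(substr(x$scheme, 1, 1), if (!is.na(x$source_mode)) paste0(",", x$source_mode))
  cat(sprintf(
    "%s[%s] = %.6g (stderr %.3g; W=%s, T_b=%s, T_w=%s, seed=%s)\n",
    x$measure, sub, x$value, x$stderr,
    x$W, x$T_b, x$T_w, x$seed
  ))
  invisible(x)
}

check_scheme <- function(scheme) {
  match.arg(scheme, c("synchronous", "asynchronous"))
}

# Per-pair contributions -> measure_result with pooled mean and stderr.
pool_result <- function(measure, scheme, source_mode, contrib, W,
                        T_b = NA_integer_, T_w = NA_integer_, seed,
                        extra = list()) {
  n <- length(contrib)
  measure_result(
    measure, scheme, source_mode,
    value = mean(contrib),
    stderr = if (n > 1L) stats::sd(contrib) / sqrt(n) else 0,
    W = W, T_b = T_b, T_w = T_w, seed = seed, extra = extra
  )
}

#' Derrida coefficient by pair sampling
#'
#' Mean Hamming distance between a trajectory and its initially single-node-
#' flipped copy after one network update: one synchronous step, or N
#' asynchronous steps on a shared schedule.  The flip target is uniform over
#' the perturbable node set of `source_mode`.
#'
#' @param net a [boolean_network()]
#' @param scheme `"synchronous"` or `"asynchronous"`
#' @param source_mode `"p"` (sources perturbable) or `"f"` (sources fixed)
#' @param n_pairs number of sampled (initial state, target) pairs
#' @param seed integer seed
#' @return a `measure_result`
#' @examples
#' derrida(parse_network("A, !A"), "synchronous", n_pairs = 100, seed = 1)
#' @export
derrida <- function(net, scheme = "synchronous", source_mode = c("p", "f"),
                    n_pairs = 100000L, seed = 1L) {
  scheme <- check_scheme(scheme)
  source_mode <- match.arg(source_mode)
  stopifnot(n_pairs >= 1L)
  targets <- match(perturbable_nodes(net, source_mode), net$nodes)
  N <- net$N
  X <- sample_initial_states(N, n_pairs, derive_seed(seed, 3L))$states
  tgt <- with_seed(
    derive_seed(seed, 4L),
    targets[sample.int(length(targets), n_pairs, replace = TRUE)]
  )
  Y <- X
  flip <- cbind(seq_len(n_pairs), tgt)
  Y[flip] <- !Y[flip]
  if (scheme == "synchronous") {
    X <- sync_step_matrix(X, net)
    Y <- sync_step_matrix(Y, net)
  } else {
    sched <- update_schedule("asynchronous", derive_seed(seed, 5L))
    for (t in seq_len(N)) {
      idx <- schedule_indices(sched, N, n_pairs, t)
      X <- async_step_matrix(X, net, idx)
      Y <- async_step_matrix(Y, net, idx)
    }
  }
  pool_result(
    "derrida", scheme, source_mode,
    contrib = rowSums(X != Y),
    W = n_pairs, seed = seed
  )
}

# Shared simulation pass behind final_hamming / fragility / quasicoherence.
# Runs W_per_target pairs for every perturbable target and returns per-pair
# contributions for all three measures, so that phi <= h_inf holds sample by
# sample, not just in expectation.
perturbation_pass <- function(net, scheme, source_mode, W_per_target,
                              T_b, T_w, eps, seed) {
  scheme <- check_scheme(scheme)
  targets <- match(perturbable_nodes(net, source_mode), net$nodes)
  if (is.null(T_b) || is.null(T_w)) {
    dw <- default_window(net$N)
    if (is.null(T_b)) T_b <- dw$T_b
    if (is.null(T_w)) T_w <- dw$T_w
  }
  if (eps >= 1 / (2 * T_w)) {
    stop("eps must be below 1/(2*T_w) to resolve fixed from oscillating nodes",
      call. = FALSE
    )
  }
  h <- phi <- q <- numeric(0)
  for (k in seq_along(targets)) {
    i <- targets[k]
    X0 <- sample_initial_states(net$N, W_per_target, derive_seed(seed, 6L, i))$states
    sched <- if (scheme == "asynchronous") {
      update_schedule("asynchronous", derive_seed(seed, 7L, i))
    } else {
      update_schedule("synchronous")
    }
    pr <- run_pair_window(net, X0, i, sched, T_b, T_w)
    h <- c(h, pr$hamming)
    phi <- c(phi, rowSums(abs(pr$mean_x - pr$mean_y)))
    sig_x <- signature_trits(pr$mean_x, eps)
    sig_y <- signature_trits(pr$mean_y, eps)
    q <- c(q, as.numeric(rowSums(sig_x != sig_y) == 0L))
  }
  list(
    h = h, phi = phi, q = q,
    scheme = scheme, source_mode = source_mode,
    W = W_per_target, T_b = T_b, T_w = T_w, seed = seed,
    n_targets = length(targets)
  )
}

# Window-mean matrix -> integer trit matrix (0 fixed-0, 1 fixed-1, 2 oscillating).
signature_trits <- function(means, eps) {
  out <- matrix(2L, nrow(means), ncol(means))
  out[means <= eps] <- 0L
  out[means >= 1 - eps] <- 1L
  out
}

#' Quasiattractor signature of window means
#'
#' @param means numeric vector or matrix of window means in \[0, 1\]
#' @param eps fixed/oscillating tolerance; a mean below `eps` is fixed-0,
#'   above `1 - eps` fixed-1, otherwise the node oscillates
#' @return character signature(s) over `{0, 1, *}`
#' @export
quasiattractor_signature <- function(means, eps = 1e-9) {
  m <- if (is.matrix(means)) means else matrix(means, nrow = 1L)
  tr <- signature_trits(m, eps)
  apply(tr, 1L, function(r) paste(c("0", "1", "*")[r + 1L], collapse = ""))
}

#' Final Hamming distance by walker simulation
#'
#' Window time-average of the per-step Hamming distance between matched pairs
#' on a shared schedule, averaged over pairs and perturbable targets.
#'
#' @inheritParams derrida
#' @param W_per_target independent initial states per perturbation target
#' @param T_b,T_w burn-in and window lengths; default 55N + 6000 total with
#'   the window the largest multiple of 4 at most half the total
#' @return a `measure_result`
#' @export
final_hamming <- function(net, scheme = "synchronous", source_mode = c("p", "f"),
                          W_per_target = 2500L, T_b = NULL, T_w = NULL,
                          seed = 1L) {
  source_mode <- match.arg(source_mode)
  p <- perturbation_pass(net, scheme, source_mode, W_per_target, T_b, T_w, 1e-9, seed)
  pool_result("final_hamming", p$scheme, source_mode, p$h, p$W, p$T_b, p$T_w, seed)
}

#' Fragility by walker simulation
#'
#' L1 distance between the window-mean state vectors of the perturbed and
#' unperturbed members of each pair (time averaging inside the norm), averaged
#' over pairs and perturbable targets.  Insensitive to phase shifts.
#'
#' @inheritParams final_hamming
#' @return a `measure_result`
#' @export
fragility <- function(net, scheme = "synchronous", source_mode = c("p", "f"),
                      W_per_target = 2500L, T_b = NULL, T_w = NULL, seed = 1L) {
  source_mode <- match.arg(source_mode)
  p <- perturbation_pass(net, scheme, source_mode, W_per_target, T_b, T_w, 1e-9, seed)
  pool_result("fragility", p$scheme, source_mode, p$phi, p$W, p$T_b, p$T_w, seed)
}

#' Quasicoherence by walker simulation
#'
#' Fraction of matched pairs whose quasiattractor signatures (fixed-0 /
#' fixed-1 / oscillating per node, derived from window means with tolerance
#' `eps`) agree exactly.
#'
#' @inheritParams final_hamming
#' @param eps signature tolerance; must be below `1/(2*T_w)`
#' @return a `measure_result`
#' @export
quasicoherence <- function(net, scheme = "synchronous", source_mode = c("p", "f"),
                           W_per_target = 2500L, T_b = NULL, T_w = NULL,
                           eps = 1e-9, seed = 1L) {
  source_mode <- match.arg(source_mode)
  p <- perturbation_pass(net, scheme, source_mode, W_per_target, T_b, T_w, eps, seed)
  pool_result("quasicoherence", p$scheme, source_mode, p$q, p$W, p$T_b, p$T_w, seed)
}

#' All three long-term measures from one shared simulation pass
#'
#' Computes final Hamming distance, fragility, and quasicoherence from the
#' same pair trajectories, guaranteeing `fragility <= final_hamming` per
#' sample.
#'
#' @inheritParams quasicoherence
#' @return named list of three `measure_result`s
#' @export
perturbation_measures <- function(net, scheme = "synchronous",
                                  source_mode = c("p", "f"),
                                  W_per_target = 2500L, T_b = NULL, T_w = NULL,
                                  eps = 1e-9, seed = 1L) {
  source_mode <- match.arg(source_mode)
  p <- perturbation_pass(net, scheme, source_mode, W_per_target, T_b, T_w, eps, seed)
  list(
    final_hamming = pool_result("final_hamming", p$scheme, source_mode, p$h, p$W, p$T_b, p$T_w, seed),
    fragility = pool_result("fragility", p$scheme, source_mode, p$phi, p$W, p$T_b, p$T_w, seed),
    quasicoherence = pool_result("quasicoherence", p$scheme, source_mode, p$q, p$W, p$T_b, p$T_w, seed)
  )
}

#' RMS difference between synchronous and asynchronous mean node values
#'
#' Evolves the same uniformly sampled initial ensemble under each update
#' scheme, takes converged ensemble-and-window mean values per node, and
#' returns the root of the mean over nodes of the squared differences.
#'
#' @param net a [boolean_network()]
#' @param W walker count
#' @param T_b,T_w burn-in and window lengths (defaults as in
#'   [final_hamming()])
#' @param seed integer seed
#' @return a `measure_result` with extra fields `mean_sync` and `mean_async`
#'   (per-node converged means) and per-scheme convergence diagnostics
#' @export
rms_update_difference <- function(net, W = 2500L, T_b = NULL, T_w = NULL, seed = 1L) {
  if (is.null(T_b) || is.null(T_w)) {
    dw <- default_window(net$N)
    if (is.null(T_b)) T_b <- dw$T_b
    if (is.null(T_w)) T_w <- dw$T_w
  }
  e0 <- sample_initial_states(net$N, W, derive_seed(seed, 8L))
  avg_s <- run_with_window(net, e0, update_schedule("synchronous"), T_b, T_w)
  avg_a <- run_with_window(
    net, e0,
    update_schedule("asynchronous", derive_seed(seed, 9L)), T_b, T_w
  )
  m_s <- colMeans(avg_s$means)
  m_a <- colMeans(avg_a$means)
  measure_result(
    "rms_update_difference",
    scheme = "both", source_mode = NA_character_,
    value = sqrt(mean((m_s - m_a)^2)),
    stderr = NA_real_,
    W = W, T_b = T_b, T_w = T_w, seed = seed,
    extra = list(
      mean_sync = m_s, mean_async = m_a,
      convergence_sync = convergence_check(avg_s),
      convergence_async = convergence_check(avg_a)
    )
  )
}
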