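# Brute-force ground truth on small networks.
#
# States are encoded as integers 0..2^N-1 with node j (in network order) on
# bit j-1.  Synchronous dynamics is a functional graph on 2^N states;
# asynchronous dynamics is a Markov chain with uniform node choice.  Paired
# perturbation dynamics under asynchronous update is a coupled chain on pair
# codes z = x + 2^N * y over 4^N states, both members updating the same
# uniformly chosen node.

.stg_cap <- 16L
.async_cap <- 6L

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a / gcd2(a, b) * b

# 2^N x N logical matrix of all states; row s+1 is state code s.
all_states <- function(N) {
  S <- matrix(FALSE, 2L^N, N)
  for (j in seq_len(N)) {
    S[, j] <- rep(rep(c(FALSE, TRUE), each = 2L^(j - 1L)), length.out = 2L^N)
  }
  S
}

encode_states <- function(M) {
  as.integer(M %*% 2^(seq_len(ncol(M)) - 1L))
}

# Update images of every state: F[s+1, j] = value of node j after updating it.
update_images <- function(net) {
  S <- all_states(net$N)
  cols <- state_cols(S)
  F <- S
  for (j in seq_len(net$N)) {
    v <- eval(net$exprs[[j]], list(.s = cols))
    F[, j] <- v
  }
  F
}

#' Build the exact state-transition graph of a small network
#'
#' @param net a [boolean_network()] with at most 16 nodes
#' @param scheme `"synchronous"` (one successor per state) or
#'   `"asynchronous"` (the N one-node-update images per state)
#' @return an `stg` object: list with `N`, `scheme`, `states` (2^N x N
#'   logical), `succ` (synchronous: integer vector of successor codes;
#'   asynchronous: 2^N x N integer matrix, column j the image under updating
#'   node j), all codes 0-based
#' @export
build_stg <- function(net, scheme = c("synchronous", "asynchronous")) {
  scheme <- match.arg(scheme)
  if (net$N > .stg_cap) {
    stop(
      "exact state-transition graph is capped at N = ", .stg_cap,
      "; use the walker simulation path for larger networks",
      call. = FALSE
    )
  }
  S <- all_states(net$N)
  F <- update_images(net)
  succ <- if (scheme == "synchronous") {
    encode_states(F)
  } else {
    codes <- seq_len(2L^net$N) - 1L
    out <- matrix(0L, 2L^net$N, net$N)
    for (j in seq_len(net$N)) {
      out[, j] <- codes + (as.integer(F[, j]) - as.integer(S[, j])) * 2L^(j - 1L)
    }
    out
  }
  structure(
    list(N = net$N, nodes = net$nodes, scheme = scheme, states = S, succ = succ),
    class = "stg"
  )
}

# Sparse one-step transition matrix of an asynchronous STG.
async_transition_matrix <- function(stg) {
  n <- 2L^stg$N
  Matrix::sparseMatrix(
    i = rep(seq_len(n), stg$N),
    j = as.vector(stg$succ) + 1L,
    x = 1 / stg$N,
    dims = c(n, n)
  )
}

# Functional-graph decomposition of a synchronous STG.
# Returns eventual cycle id per state, list of cycles (0-based codes, in
# order), cycle lengths, cycle mean vectors, and cycle signature trits.
sync_cycles <- function(stg) {
  succ <- stg$succ
  n <- length(succ)
  color <- integer(n)
  eventual <- integer(n)
  cycles <- list()
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    path <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- succ[v] + 1L
    }
    if (color[v] == 1L) {
      k <- match(v, path)
      cyc <- path[k:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc - 1L
      eventual[path] <- length(cycles)
    } else {
      eventual[path] <- eventual[v]
    }
    color[path] <- 2L
  }
  lens <- lengths(cycles)
  means <- do.call(rbind, lapply(cycles, function(cyc) {
    colMeans(stg$states[cyc + 1L, , drop = FALSE])
  }))
  trits <- matrix(2L, length(cycles), stg$N)
  trits[means == 0] <- 0L
  trits[means == 1] <- 1L
  list(eventual = eventual, cycles = cycles, lengths = lens, means = means, trits = trits)
}

#' Exact attractors, basins, and absorption probabilities
#'
#' Attractors are the terminal strongly connected components of the state
#' transition graph.  Under synchronous update every state belongs to exactly
#' one basin; under asynchronous update each state carries a vector of exact
#' absorption probabilities into the attractors, solved from the
#' uniform-node-choice transition matrix.
#'
#' @param stg an `stg` from [build_stg()]
#' @return an `attractor_set`: list with `attractors` (list of 0-based state
#'   code vectors), `scheme`, `basin` (synchronous: attractor index per
#'   state), `basin_fractions`, and `absorption` (asynchronous: 2^N x
#'   n_attractor matrix of absorption probabilities)
#' @export
find_attractors <- function(stg) {
  stopifnot(inherits(stg, "stg"))
  n <- 2L^stg$N
  if (stg$scheme == "synchronous") {
    cy <- sync_cycles(stg)
    out <- list(
      attractors = cy$cycles,
      scheme = "synchronous",
      basin = cy$eventual,
      basin_fractions = as.vector(table(factor(cy$eventual, levels = seq_along(cy$cycles)))) / n,
      absorption = NULL,
      stg = stg
    )
  } else {
    from <- rep(seq_len(n), stg$N)
    to <- as.vector(stg$succ) + 1L
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    memb <- igraph::components(g, mode = "strong")$membership
    leaving <- unique(memb[from[memb[from] != memb[to]]])
    terminal <- setdiff(unique(memb), leaving)
    attractors <- lapply(terminal, function(k) which(memb == k) - 1L)
    P <- async_transition_matrix(stg)
    absorption <- absorption_probabilities(P, lapply(attractors, function(a) a + 1L))
    out <- list(
      attractors = attractors,
      scheme = "asynchronous",
      basin = NULL,
      basin_fractions = colMeans(absorption),
      absorption = absorption,
      stg = stg
    )
  }
  structure(out, class = "attractor_set")
}

# Absorption probabilities into closed classes of a finite chain.
# classes: list of 1-based state index vectors (disjoint, closed).
absorption_probabilities <- function(P, classes) {
  n <- nrow(P)
  K <- length(classes)
  A <- matrix(0, n, K)
  for (k in seq_len(K)) A[classes[[k]], k] <- 1
  trans <- setdiff(seq_len(n), unlist(classes))
  if (length(trans)) {
    M <- Matrix::Diagonal(length(trans)) - P[trans, trans, drop = FALSE]
    R <- matrix(0, length(trans), K)
    for (k in seq_len(K)) {
      R[, k] <- Matrix::rowSums(P[trans, classes[[k]], drop = FALSE])
    }
    A[trans, ] <- as.matrix(Matrix::solve(M, R))
  }
  A
}

# Stationary distribution of a closed communicating class (irreducible).
class_stationary <- function(P, class_idx) {
  m <- length(class_idx)
  if (m == 1L) {
    return(1)
  }
  M <- Matrix::t(P[class_idx, class_idx, drop = FALSE]) - Matrix::Diagonal(m)
  M[m, ] <- 1
  b <- c(rep(0, m - 1L), 1)
  as.vector(Matrix::solve(M, b))
}

# Terminal SCC decomposition of a sparse chain.
terminal_classes <- function(P) {
  n <- nrow(P)
  TP <- as(P, "TsparseMatrix")
  from <- TP@i + 1L
  to <- TP@j + 1L
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g, mode = "strong")$membership
  leaving <- unique(memb[from[memb[from] != memb[to]]])
  terminal <- setdiff(unique(memb), leaving)
  lapply(terminal, function(k) which(memb == k))
}

#' Quasiattractor signatures of an attractor set
#'
#' A node fixed at 0 (1) across every state of an attractor contributes `0`
#' (`1`) to the signature; a node taking both values oscillates and
#' contributes `*`.  Attractors sharing a signature are merged.
#'
#' @param attrs an `attractor_set` from [find_attractors()]
#' @return list with `signatures` (unique signature strings, in first-
#'   appearance order) and `of_attractor` (signature of each attractor)
#' @export
quasiattractors <- function(attrs) {
  stopifnot(inherits(attrs, "attractor_set"))
  S <- attrs$stg$states
  sig <- vapply(attrs$attractors, function(cyc) {
    M <- S[cyc + 1L, , drop = FALSE]
    m <- colMeans(M)
    paste(ifelse(m == 0, "0", ifelse(m == 1, "1", "*")), collapse = "")
  }, character(1))
  list(signatures = unique(sig), of_attractor = sig)
}

# ---- Exact measures, synchronous --------------------------------------------

#' Exact perturbation measures under synchronous update
#'
#' Enumerates all 2^N initial states and all perturbable flip targets.  Each
#' deterministic pair trajectory is followed onto its joint cycle; the final
#' Hamming distance is the exact cycle average, fragility the L1 distance of
#' the two members' exact cycle means, quasicoherence the indicator that the
#' members' cycle signatures agree, and the Derrida coefficient the Hamming
#' distance after one step.
#'
#' @param net a [boolean_network()] with at most 16 nodes
#' @param source_mode `"p"` or `"f"` (see [perturbable_nodes()])
#' @return named list with exact `derrida`, `final_hamming`, `fragility`,
#'   `quasicoherence`
#' @examples
#' exact_measures_sync(parse_network("A, !A"))
#' @export
exact_measures_sync <- function(net, source_mode = c("p", "f")) {
  source_mode <- match.arg(source_mode)
  stg <- build_stg(net, "synchronous")
  cy <- sync_cycles(stg)
  targets <- match(perturbable_nodes(net, source_mode), net$nodes)
  n <- 2L^net$N
  codes <- seq_len(n) - 1L
  bitcount <- rowSums(stg$states)

  xs <- rep(codes, times = length(targets))
  ys <- as.integer(bitwXor(xs, rep(2L^(targets - 1L), each = n)))

  d_vals <- bitcount[bitwXor(stg$succ[xs + 1L], stg$succ[ys + 1L]) + 1L]

  # advance every pair onto its joint cycle (tail length < 2^N)
  x <- xs
  y <- ys
  for (t in seq_len(n)) {
    x <- stg$succ[x + 1L]
    y <- stg$succ[y + 1L]
  }
  cx <- cy$eventual[x + 1L]
  cyid <- cy$eventual[y + 1L]
  L_pair <- mapply(lcm2, cy$lengths[cx], cy$lengths[cyid])
  L_all <- Reduce(lcm2, unique(L_pair), accumulate = FALSE)
  hsum <- numeric(length(x))
  for (t in seq_len(L_all)) {
    hsum <- hsum + bitcount[bitwXor(x, y) + 1L]
    x <- stg$succ[x + 1L]
    y <- stg$succ[y + 1L]
  }
  h_vals <- hsum / L_all
  phi_vals <- rowSums(abs(cy$means[cx, , drop = FALSE] - cy$means[cyid, , drop = FALSE]))
  q_vals <- as.numeric(rowSums(
    cy$trits[cx, , drop = FALSE] != cy$trits[cyid, , drop = FALSE]
  ) == 0L)
  list(
    derrida = mean(d_vals),
    final_hamming = mean(h_vals),
    fragility = mean(phi_vals),
    quasicoherence = mean(q_vals)
  )
}

#' Exact long-run mean node values
#'
#' Cesàro (long-run time-average) expectation of every node value, averaged
#' over uniformly sampled initial states.  Synchronous: exact cycle averages
#' of the deterministic trajectory from each state.  Asynchronous: stationary
#' averages of the closed communicating classes of the uniform-node-choice
#' chain, weighted by exact absorption probabilities.
#'
#' @param net a [boolean_network()]
#' @param scheme update scheme
#' @return named numeric vector of per-node long-run means
#' @export
exact_node_means <- function(net, scheme = c("synchronous", "asynchronous")) {
  scheme <- match.arg(scheme)
  stg <- build_stg(net, scheme)
  if (scheme == "synchronous") {
    cy <- sync_cycles(stg)
    m <- colMeans(cy$means[cy$eventual, , drop = FALSE])
  } else {
    P <- async_transition_matrix(stg)
    classes <- terminal_classes(P)
    class_means <- do.call(rbind, lapply(classes, function(cl) {
      pi_c <- class_stationary(P, cl)
      as.vector(pi_c %*% stg$states[cl, , drop = FALSE])
    }))
    A <- absorption_probabilities(P, classes)
    m <- pmin(pmax(colMeans(A %*% class_means), 0), 1)
  }
  stats::setNames(as.vector(m), net$nodes)
}

# ---- Exact measures, asynchronous -------------------------------------------

#' Exact perturbation measures under asynchronous update
#'
#' Builds the coupled Markov chain on trajectory pairs (4^N pair states, both
#' members updating the same uniformly chosen node), then computes for every
#' enumerated initial pair the exact long-run expectations via stationary
#' distributions of the closed classes and absorption probabilities.  The
#' Derrida coefficient uses exactly N steps of the pair chain.
#'
#' @param net a [boolean_network()] with at most 6 nodes
#' @param source_mode `"p"` or `"f"`
#' @return named list with exact `derrida`, `final_hamming`, `fragility`,
#'   `quasicoherence`
#' @export
exact_measures_async <- function(net, source_mode = c("p", "f")) {
  source_mode <- match.arg(source_mode)
  if (net$N > .async_cap) {
    stop(
      "exact asynchronous measures are capped at N = ", .async_cap,
      " (the pair chain has 4^N states); use the walker estimates instead",
      call. = FALSE
    )
  }
  stg <- build_stg(net, "asynchronous")
  N <- net$N
  n <- 2L^N
  npair <- n * n
  zx <- rep(seq_len(n) - 1L, times = n)
  zy <- rep(seq_len(n) - 1L, each = n)

  # coupled chain: shared node choice j with probability 1/N
  ii <- jj <- integer(0)
  for (j in seq_len(N)) {
    ii <- c(ii, seq_len(npair))
    jj <- c(jj, stg$succ[zx + 1L, j] + n * stg$succ[zy + 1L, j] + 1L)
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / N, dims = c(npair, npair))

  bitcount <- rowSums(stg$states)
  hvec <- bitcount[bitwXor(zx, zy) + 1L]

  targets <- match(perturbable_nodes(net, source_mode), net$nodes)
  x0 <- rep(seq_len(n) - 1L, times = length(targets))
  y0 <- as.integer(bitwXor(x0, rep(2L^(targets - 1L), each = n)))
  z0 <- x0 + n * y0 + 1L

  # Derrida: N-step expectation of the Hamming distance
  v <- hvec
  for (t in seq_len(N)) v <- as.vector(P %*% v)
  d_vals <- v[z0]

  classes <- terminal_classes(P)
  class_h <- numeric(length(classes))
  class_phi <- numeric(length(classes))
  class_q <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[[k]]
    pi_c <- class_stationary(P, cl)
    class_h[k] <- sum(pi_c * hvec[cl])
    Mx <- stg$states[zx[cl] + 1L, , drop = FALSE]
    My <- stg$states[zy[cl] + 1L, , drop = FALSE]
    mx <- as.vector(pi_c %*% Mx)
    my <- as.vector(pi_c %*% My)
    class_phi[k] <- sum(abs(mx - my))
    # a node is fixed in a member iff its bit is constant across the class
    tx <- ifelse(colMeans(Mx) == 0, 0L, ifelse(colMeans(Mx) == 1, 1L, 2L))
    ty <- ifelse(colMeans(My) == 0, 0L, ifelse(colMeans(My) == 1, 1L, 2L))
    class_q[k] <- as.numeric(all(tx == ty))
  }
  A <- absorption_probabilities(P, classes)
  h_vals <- as.vector(A %*% class_h)[z0]
  phi_vals <- as.vector(A %*% class_phi)[z0]
  q_vals <- as.vector(A %*% class_q)[z0]
  # linear solves leave O(1e-16) residue; clamp to the mathematical ranges
  list(
    derrida = max(mean(d_vals), 0),
    final_hamming = max(mean(h_vals), 0),
    fragility = max(mean(phi_vals), 0),
    quasicoherence = min(max(mean(q_vals), 0), 1)
  )
}

#' Exact measures for either update scheme
#'
#' @param net a [boolean_network()]
#' @param scheme update scheme
#' @param source_mode `"p"` or `"f"`
#' @return named list with `derrida`, `final_hamming`, `fragility`,
#'   `quasicoherence`
#' @export
exact_measures <- function(net, scheme = c("synchronous", "asynchronous"),
                           source_mode = c("p", "f")) {
  scheme <- match.arg(scheme)
  if (scheme == "synchronous") {
    exact_measures_sync(net, source_mode)
  } else {
    exact_measures_async(net, source_mode)
  }
}

#' Serialize an attractor report as plain data
#'
#' @param attrs an `attractor_set`
#' @return list (JSON-ready) with attractor states as bitstrings in node
#'   order, basin fractions, and quasiattractor signatures
#' @export
attractor_report <- function(attrs) {
  stopifnot(inherits(attrs, "attractor_set"))
  S <- attrs$stg$states
  qa <- quasiattractors(attrs)
  list(
    scheme = attrs$scheme,
    n_attractors = length(attrs$attractors),
    attractors = lapply(attrs$attractors, function(cyc) {
      apply(S[cyc + 1L, , drop = FALSE], 1L, function(r) {
        paste(as.integer(r), collapse = "")
      })
    }),
    basin_fractions = as.vector(attrs$basin_fractions),
    quasiattractors = qa$signatures,
    quasiattractor_of_attractor = qa$of_attractor
  )
}
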