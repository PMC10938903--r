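# Kauffman NK random Boolean networks and built-in worked-example fixtures.

#' Specify a Kauffman NK random Boolean network ensemble
#'
#' Each node receives K distinct regulators drawn uniformly from all N nodes
#' (self allowed) and an update truth table drawn uniformly from all 2^(2^K)
#' Boolean functions of its inputs.
#'
#' @param N node count
#' @param K in-degree per node, `1 <= K <= N`
#' @return an `rbn_spec` object
#' @export
rbn_spec <- function(N, K) {
  if (K > N) stop("K must not exceed N", call. = FALSE)
  if (K < 1L || N < 1L) stop("need N >= K >= 1", call. = FALSE)
  structure(list(N = as.integer(N), K = as.integer(K)), class = "rbn_spec")
}

# Truth table (logical, length 2^K, input 1 fastest bit) -> AST over inputs.
table_to_ast <- function(tab, inputs) {
  if (!any(tab)) {
    return(ast_const(FALSE))
  }
  if (all(tab)) {
    return(ast_const(TRUE))
  }
  k <- length(inputs)
  minterms <- lapply(which(tab) - 1L, function(row) {
    lits <- lapply(seq_len(k), function(b) {
      v <- ast_var(inputs[b])
      if (bitwAnd(row, 2L^(b - 1L)) > 0L) v else ast_not(v)
    })
    Reduce(ast_and, lits)
  })
  Reduce(ast_or, minterms)
}

#' Sample one NK random Boolean network
#'
#' @param spec an [rbn_spec()]
#' @param seed integer seed; the same seed reproduces the same network
#' @return a [boolean_network()] whose sampled truth tables are attached as
#'   attribute `"tables"` (list of `list(inputs, table)` per node)
#' @export
generate_rbn <- function(spec, seed) {
  stopifnot(inherits(spec, "rbn_spec"))
  N <- spec$N
  K <- spec$K
  nodes <- paste0("n", seq_len(N))
  samp <- with_seed(derive_seed(seed, 10L), {
    lapply(seq_len(N), function(j) {
      list(
        inputs = nodes[sample.int(N, K)],
        table = sample(c(FALSE, TRUE), 2L^K, replace = TRUE)
      )
    })
  })
  net <- boolean_network(
    nodes,
    lapply(samp, function(s) table_to_ast(s$table, s$inputs))
  )
  attr(net, "tables") <- samp
  net
}

#' Fraction of NK networks without any source node
#'
#' Samples `n_networks` networks from the ensemble, classifies every node
#' semantically, and reports the fraction of networks with zero source nodes
#' together with an exact (Clopper-Pearson) binomial confidence interval.
#'
#' @param spec an [rbn_spec()]
#' @param n_networks number of sampled networks (>= 100)
#' @param seed integer seed
#' @param conf_level confidence level of the interval
#' @return list with `fraction`, `ci` (length-2 vector), `n_networks`, and
#'   the per-network `source_counts` and `constant_counts`
#' @export
source_free_fraction <- function(spec, n_networks = 10000L, seed = 1L,
                                 conf_level = 0.95) {
  stopifnot(inherits(spec, "rbn_spec"), n_networks >= 100L)
  src <- integer(n_networks)
  cst <- integer(n_networks)
  for (r in seq_len(n_networks)) {
    net <- generate_rbn(spec, derive_seed(seed, 11L, r))
    cls <- classify_nodes(net)
    src[r] <- sum(cls == "source")
    cst[r] <- sum(cls == "constant")
  }
  k <- sum(src == 0L)
  ci <- stats::binom.test(k, n_networks, conf.level = conf_level)$conf.int
  list(
    fraction = k / n_networks,
    ci = as.vector(ci),
    n_networks = n_networks,
    source_counts = src,
    constant_counts = cst
  )
}

.fixture_rules <- list(
  oscillator = "A, !A",
  oscillator_plus_source = "A, !A\nB, B",
  mutual_inhibition = "A, !B\nB, !A",
  three_cycle = "A, B\nB, C\nC, A",
  all_constant = "A, 0\nB, 1"
)

#' Built-in worked-example fixture networks
#'
#' `oscillator` is the one-node negation oscillator; `oscillator_plus_source`
#' adds an independent source node; `mutual_inhibition` is the two-gene
#' mutual-inhibition motif; `three_cycle` is the three-node rotation; and
#' `all_constant` has two constant nodes.
#'
#' @param name one of `"oscillator"`, `"oscillator_plus_source"`,
#'   `"mutual_inhibition"`, `"three_cycle"`, `"all_constant"`
#' @return a [boolean_network()]
#' @examples
#' fixture("mutual_inhibition")
#' @export
fixture <- function(name) {
  if (!name %in% names(.fixture_rules)) {
    stop(
      "unknown fixture '", name, "'; available: ",
      paste(names(.fixture_rules), collapse = ", "),
      call. = FALSE
    )
  }
  parse_network(.fixture_rules[[name]])
}

#' Names of the built-in fixtures
#' @return character vector
#' @export
fixture_names <- function() names(.fixture_rules)
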