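# Semantic node classification and network reduction.
#
# Classification is by truth-table equivalence over a rule's referenced
# inputs, never by syntax: "A | !A" is constant, "(B & A) | (!B & A)" is a
# source for node A.  Fan-in is bounded at 20 referenced inputs.

.max_fanin <- 20L

# Truth table of rule j over its referenced inputs.
# Returns list(vars, table): `table[k]` is the rule value on the k-th
# assignment, assignments enumerated with vars[1] as the fastest bit.
rule_truth_table <- function(net, j) {
  ast <- net$rules[[j]]
  vars <- ast_vars(ast)
  k <- length(vars)
  if (k > .max_fanin) {
    stop("rule for '", net$nodes[j], "' references ", k,
      " inputs; semantic classification is capped at ", .max_fanin,
      call. = FALSE
    )
  }
  n_assign <- 2L^k
  cols <- lapply(seq_len(k), function(b) {
    rep(rep(c(FALSE, TRUE), each = 2L^(b - 1L)), length.out = n_assign)
  })
  expr <- compile_ast(ast, stats::setNames(seq_len(max(k, 1L)), vars))
  out <- eval(expr, list(.s = cols))
  if (length(out) == 1L) out <- rep(out, n_assign)
  list(vars = vars, table = out)
}

#' Classify nodes as constant, source, or internal
#'
#' A node is `constant` when its update rule evaluates to the same value on
#' every input assignment, `source` when the rule is logically equivalent to
#' the node's own current value, and `internal` otherwise.  The test is
#' semantic (truth-table equivalence over referenced inputs), so logically
#' equivalent rewrites of a rule classify identically.
#'
#' @param net a [boolean_network()]
#' @return character vector (one of `"constant"`, `"source"`, `"internal"`)
#'   named by node
#' @examples
#' classify_nodes(parse_network("A, !A\nB, B\nC, 1"))
#' @export
classify_nodes <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  out <- character(net$N)
  for (j in seq_len(net$N)) {
    tt <- rule_truth_table(net, j)
    out[j] <- if (all(tt$table) || !any(tt$table)) {
      "constant"
    } else if (net$nodes[j] %in% tt$vars) {
      b <- match(net$nodes[j], tt$vars)
      self_col <- rep(rep(c(FALSE, TRUE), each = 2L^(b - 1L)),
        length.out = length(tt$table)
      )
      if (identical(tt$table, self_col)) "source" else "internal"
    } else {
      "internal"
    }
  }
  stats::setNames(out, net$nodes)
}

# Constant value of a semantically constant rule (assumes constancy checked).
rule_constant_value <- function(net, j) {
  rule_truth_table(net, j)$table[1]
}

#' Percolate fixed source/constant values through a network
#'
#' Substitutes the given values into every rule, then repeatedly fixes any
#' node whose rule has become (or already was) semantically constant, until no
#' new node is fixed.  The dynamics of the surviving nodes are unchanged for
#' initial states consistent with the fixed values.
#'
#' @param net a [boolean_network()]
#' @param source_values named vector (or list) of 0/1 values; every name must
#'   be a source or constant node
#' @return list with `core` (the reduced [boolean_network()], or `NULL` when
#'   every node percolates) and `fixed` (named 0/1 integer vector of all nodes
#'   fixed, in node order)
#' @export
percolate_sources <- function(net, source_values = c()) {
  stopifnot(inherits(net, "boolean_network"))
  vals <- unlist(source_values)
  cls <- classify_nodes(net)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
      stop("source_values must be named by node", call. = FALSE)
    }
    bad <- setdiff(names(vals), net$nodes)
    if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
    internal <- names(vals)[cls[names(vals)] == "internal"]
    if (length(internal)) {
      stop("cannot fix internal node(s): ", paste(internal, collapse = ", "),
        call. = FALSE
      )
    }
    for (nm in names(vals)[cls[names(vals)] == "constant"]) {
      cval <- rule_constant_value(net, match(nm, net$nodes))
      if (as.logical(vals[[nm]]) != cval) {
        stop("value for constant node '", nm, "' contradicts its rule", call. = FALSE)
      }
    }
  }
  fixed <- stats::setNames(as.logical(vals), names(vals))
  remaining <- net
  repeat {
    subs <- lapply(fixed, ast_const)
    keep <- setdiff(remaining$nodes, names(fixed))
    if (length(keep) == 0L) {
      remaining <- NULL
      break
    }
    rules <- lapply(match(keep, remaining$nodes), function(j) {
      simplify_ast(substitute_ast(remaining$rules[[j]], subs))
    })
    remaining <- boolean_network(keep, rules)
    newly <- character(0)
    for (j in seq_len(remaining$N)) {
      tt <- rule_truth_table(remaining, j)
      if (all(tt$table) || !any(tt$table)) {
        fixed[[remaining$nodes[j]]] <- tt$table[1]
        newly <- c(newly, remaining$nodes[j])
      }
    }
    if (length(newly) == 0L) break
  }
  ord <- intersect(net$nodes, names(fixed))
  list(
    core = remaining,
    fixed = stats::setNames(as.integer(fixed[ord]), ord)
  )
}

#' Eliminate a self-edge-free node by inlining its update rule
#'
#' The node's rule is substituted for every occurrence of the node in the
#' remaining rules and the node is dropped.  Steady states of the reduced
#' network correspond one-to-one to steady states of the original restricted
#' to the surviving nodes.
#'
#' @param net a [boolean_network()]
#' @param node identifier of the node to eliminate; its rule must not
#'   reference the node itself
#' @return the reduced [boolean_network()]
#' @export
eliminate_node <- function(net, node) {
  stopifnot(inherits(net, "boolean_network"))
  j <- match(node, net$nodes)
  if (is.na(j)) stop("unknown node: ", node, call. = FALSE)
  if (node %in% ast_vars(net$rules[[j]])) {
    stop("node '", node, "' has a self-edge and cannot be eliminated", call. = FALSE)
  }
  if (net$N == 1L) stop("cannot eliminate the only node", call. = FALSE)
  subs <- stats::setNames(list(net$rules[[j]]), node)
  keep <- setdiff(seq_len(net$N), j)
  boolean_network(
    net$nodes[keep],
    lapply(net$rules[keep], function(r) simplify_ast(substitute_ast(r, subs)))
  )
}

#' Names of perturbable nodes under a source-handling mode
#'
#' In mode `"p"` every node is a perturbation target; in mode `"f"` (fixed
#' sources) source nodes are excluded, while constant nodes and nodes fixed
#' downstream of sources remain perturbable.
#'
#' @param net a [boolean_network()]
#' @param source_mode `"p"` (perturbable sources) or `"f"` (fixed sources)
#' @return character vector of node names
#' @export
perturbable_nodes <- function(net, source_mode = c("p", "f")) {
  source_mode <- match.arg(source_mode)
  if (source_mode == "p") {
    return(net$nodes)
  }
  cls <- classify_nodes(net)
  out <- net$nodes[cls != "source"]
  if (length(out) == 0L) {
    stop("fixed-source mode has no perturbable target: all nodes are sources",
      call. = FALSE
    )
  }
  out
}
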