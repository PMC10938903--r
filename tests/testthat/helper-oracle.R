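# Independent reference evaluation of rule text, bypassing the package's
# tokenizer/AST entirely: operator words are rewritten to R operators and the
# result is evaluated by R's own parser.
ref_rule_fun <- function(expr_text) {
  s <- gsub("\\bAND\\b", "&", expr_text, ignore.case = TRUE)
  s <- gsub("\\bOR\\b", "|", s, ignore.case = TRUE)
  s <- gsub("\\bNOT\\b", "!", s, ignore.case = TRUE)
  e <- parse(text = s)[[1]]
  function(assignment) {
    as.logical(eval(e, lapply(assignment, as.logical)))
  }
}

# All 2^k assignments over `vars` as a list of named logical vectors.
all_assignments <- function(vars) {
  k <- length(vars)
  lapply(seq_len(2^k) - 1L, function(code) {
    stats::setNames(as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0), vars)
  })
}

# Truth-table equality of two parsed networks (same nodes assumed), checked
# through the synchronous state-transition graph.
expect_same_dynamics <- function(net1, net2) {
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(
    build_stg(net1, "synchronous")$succ,
    build_stg(net2, "synchronous")$succ
  )
}

ast_vars_of <- function(net, j) walkerbn:::ast_vars(net$rules[[j]])

# Sorted multiset of point-attractor states (as bitstrings over `nodes`)
# of a network under synchronous update.
steady_states <- function(net) {
  at <- find_attractors(build_stg(net, "synchronous"))
  pts <- Filter(function(a) length(a) == 1L, at$attractors)
  sort(vapply(pts, function(a) {
    paste(as.integer(at$stg$states[a + 1L, ]), collapse = "")
  }, character(1)))
}
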