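test_that("parsed rules match reference evaluation on every assignment", {
  cases <- list(
    list(text = "A, !B\nB, !A", rules = c(A = "!B", B = "!A")),
    list(text = "A = B AND NOT C\nB, C or A\nC, 1", rules = c(A = "B & !C", B = "C | A", C = "1")),
    list(
      text = "# comment line\ntargets, factors\nA, (B & !B) | (A AND A)\nB, not (A or B)",
      rules = c(A = "(B & !B) | (A & A)", B = "!(A | B)")
    )
  )
  for (case in cases) {
    net <- parse_network(case$text)
    expect_identical(net$nodes, names(case$rules))
    for (assignment in all_assignments(net$nodes)) {
      cols <- lapply(assignment, identity)
      for (j in seq_len(net$N)) {
        ref <- ref_rule_fun(case$rules[[net$nodes[j]]])(assignment)
        got <- eval(net$exprs[[j]], list(.s = unname(cols)))
        expect_identical(as.logical(got), ref,
          info = paste(net$nodes[j], paste(as.integer(assignment), collapse = ""))
        )
      }
    }
  }
})

test_that("parse errors name the offender", {
  expect_error(parse_network("A, !B"), "undeclared identifier.*B")
  expect_error(parse_network("A, A\nA, !A"), "duplicate target 'A'")
  expect_error(parse_network("# only a comment\n"), "empty")
  expect_error(parse_network("A, B &\nB, A"), "unexpected end")
  expect_error(parse_network("A, @"), "unexpected character")
})

test_that("classification is semantic, not syntactic", {
  net <- parse_network("A, A\nB, (C & B) | (!C & B)\nC, C | !C\nD, C & !C\nE, !C")
  cls <- classify_nodes(net)
  expect_identical(unname(cls), c("source", "source", "constant", "constant", "internal"))
  # worked examples
  expect_identical(unname(classify_nodes(parse_network("A, !B\nB, !A"))), rep("internal", 2))
  expect_identical(unname(classify_nodes(parse_network("A, !A\nB, B"))["B"]), "source")
  expect_identical(unname(classify_nodes(parse_network("A, A | !A"))), "constant")
  expect_identical(unname(classify_nodes(parse_network("A, (B & !B)\nB, B"))["A"]), "constant")
})

test_that("classification is invariant under logically equivalent rewrites", {
  set.seed(41)
  for (k in 1:20) {
    net <- generate_rbn(rbn_spec(4, 2), seed = 7000 + k)
    base <- classify_nodes(net)
    txt <- format_network(net)
    lines <- strsplit(txt, "\n")[[1]]
    parts <- regmatches(lines, regexec("^([^,]+), (.*)$", lines))
    rewritten <- vapply(parts, function(p) {
      # double negation plus a tautological conjunct
      paste0(trimws(p[2]), ", !(!(", p[3], ")) & (n1 | !n1)")
    }, character(1))
    net2 <- parse_network(paste(rewritten, collapse = "\n"))
    expect_identical(classify_nodes(net2), base)
  }
})

test_that("parse -> serialize -> parse round-trips the dynamics", {
  fixtures <- lapply(fixture_names(), fixture)
  set.seed(5)
  randoms <- lapply(1:10, function(k) generate_rbn(rbn_spec(4, 2), seed = 300 + k))
  for (net in c(fixtures, randoms)) {
    expect_same_dynamics(net, parse_network(format_network(net)))
  }
})

test_that("percolate_sources iterates until no rule is newly constant", {
  res <- percolate_sources(parse_network("A, A\nB, A & C\nC, B"), c(A = 0))
  expect_null(res$core)
  expect_identical(res$fixed, c(A = 0L, B = 0L, C = 0L))

  res <- percolate_sources(parse_network("A, A\nB, !B"), c(A = 1))
  expect_identical(res$fixed, c(A = 1L))
  expect_identical(res$core$nodes, "B")
  expect_same_dynamics(res$core, parse_network("B, !B"))

  res <- percolate_sources(fixture("mutual_inhibition"))
  expect_length(res$fixed, 0L)
  expect_same_dynamics(res$core, fixture("mutual_inhibition"))

  expect_error(
    percolate_sources(fixture("mutual_inhibition"), c(A = 1)),
    "internal"
  )
  expect_error(
    percolate_sources(fixture("all_constant"), c(A = 1)),
    "contradicts"
  )
})

test_that("eliminate_node inlines the rule and preserves steady states", {
  net <- parse_network("A, B\nB, C\nC, A")
  red <- eliminate_node(net, "B")
  expect_identical(red$nodes, c("A", "C"))
  expect_same_dynamics(red, parse_network("A, C\nC, A"))

  expect_error(eliminate_node(parse_network("A, !A\nB, A"), "A"), "self-edge")

  net <- parse_network("A, B & C\nB, !C\nC, C")
  red <- eliminate_node(net, "B")
  expect_identical(unname(classify_nodes(red)["A"]), "constant")

  # steady-state preservation on random self-edge-free eliminations
  set.seed(19)
  checked <- 0
  for (k in 1:30) {
    net <- generate_rbn(rbn_spec(4, 2), seed = 9000 + k)
    ok <- vapply(seq_len(net$N), function(j) {
      !(net$nodes[j] %in% ast_vars_of(net, j))
    }, logical(1))
    j <- which(ok)[1]
    if (is.na(j)) next
    red <- eliminate_node(net, net$nodes[j])
    ss_red <- steady_states(red)
    keep <- match(red$nodes, net$nodes)
    ss_orig <- unique(vapply(
      strsplit(steady_states(net), ""),
      function(b) paste(b[keep], collapse = ""), character(1)
    ))
    expect_identical(sort(ss_orig), ss_red)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("percolation preserves projected steady states", {
  # networks with a genuine source node
  nets <- list(
    parse_network("S, S\nA, S & !B\nB, !A\nC, A | B"),
    parse_network("S, S\nA, !S | B\nB, A & S")
  )
  for (net in nets) {
    for (v in 0:1) {
      res <- percolate_sources(net, c(S = v))
      ss_all <- steady_states(net)
      keepbit <- v == 1
      ss_match <- ss_all[substr(ss_all, 1, 1) == as.integer(keepbit)]
      if (is.null(res$core)) {
        fixed_str <- paste(res$fixed[net$nodes], collapse = "")
        expect_identical(ss_match, fixed_str)
      } else {
        keep <- match(res$core$nodes, net$nodes)
        proj <- sort(unique(vapply(
          strsplit(ss_match, ""),
          function(b) paste(b[keep], collapse = ""), character(1)
        )))
        expect_identical(proj, steady_states(res$core))
      }
    }
  }
})
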