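# ---- Boolean expression trees ------------------------------------------------
#
# A rule is stored as a plain-list AST:
#   list(op = "var",   name  = <chr>)
#   list(op = "const", value = <lgl>)
#   list(op = "not",   x     = <ast>)
#   list(op = "and"|"or", lhs = <ast>, rhs = <ast>)
# ASTs are compiled to R language objects over a list of state columns `.s`
# for vectorised evaluation across walkers.

ast_var <- function(name) list(op = "var", name = name)
ast_const <- function(value) list(op = "const", value = isTRUE(value))
ast_not <- function(x) list(op = "not", x = x)
ast_and <- function(lhs, rhs) list(op = "and", lhs = lhs, rhs = rhs)
ast_or <- function(lhs, rhs) list(op = "or", lhs = lhs, rhs = rhs)

#' Collect node identifiers referenced by an expression tree
#' @param ast a rule expression tree
#' @return character vector of unique identifiers, in first-appearance order
#' @keywords internal
ast_vars <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = character(0),
    not = ast_vars(ast$x),
    unique(c(ast_vars(ast$lhs), ast_vars(ast$rhs)))
  )
}

# Compile an AST to an R call over `.s[[j]]`, j given by `index` (named ints).
compile_ast <- function(ast, index) {
  switch(ast$op,
    var = {
      j <- index[[ast$name]]
      if (is.null(j) || is.na(j)) {
        stop("unknown identifier in rule: ", ast$name, call. = FALSE)
      }
      call("[[", quote(.s), as.integer(j))
    },
    const = ast$value,
    not = call("!", compile_ast(ast$x, index)),
    and = call("&", compile_ast(ast$lhs, index), compile_ast(ast$rhs, index)),
    or = call("|", compile_ast(ast$lhs, index), compile_ast(ast$rhs, index))
  )
}

# Substitute variables by other ASTs (named list), leaving the rest intact.
substitute_ast <- function(ast, subs) {
  switch(ast$op,
    var = if (!is.null(subs[[ast$name]])) subs[[ast$name]] else ast,
    const = ast,
    not = ast_not(substitute_ast(ast$x, subs)),
    and = ast_and(substitute_ast(ast$lhs, subs), substitute_ast(ast$rhs, subs)),
    or = ast_or(substitute_ast(ast$lhs, subs), substitute_ast(ast$rhs, subs))
  )
}

# Constant folding only; semantic questions go through truth tables.
simplify_ast <- function(ast) {
  switch(ast$op,
    var = ast,
    const = ast,
    not = {
      x <- simplify_ast(ast$x)
      if (x$op == "const") ast_const(!x$value) else ast_not(x)
    },
    and = {
      l <- simplify_ast(ast$lhs)
      r <- simplify_ast(ast$rhs)
      if (l$op == "const") {
        if (l$value) r else ast_const(FALSE)
      } else if (r$op == "const") {
        if (r$value) l else ast_const(FALSE)
      } else {
        ast_and(l, r)
      }
    },
    or = {
      l <- simplify_ast(ast$lhs)
      r <- simplify_ast(ast$rhs)
      if (l$op == "const") {
        if (l$value) ast_const(TRUE) else r
      } else if (r$op == "const") {
        if (r$value) ast_const(TRUE) else l
      } else {
        ast_or(l, r)
      }
    }
  )
}

# Render an AST back to rule-file syntax (minimal parentheses).
# Precedence: or (1) < and (2) < not (3).
ast_deparse <- function(ast, parent_prec = 0L) {
  out <- switch(ast$op,
    var = ast$name,
    const = if (ast$value) "1" else "0",
    not = paste0("!", ast_deparse(ast$x, 3L)),
    and = paste0(ast_deparse(ast$lhs, 2L), " & ", ast_deparse(ast$rhs, 2L)),
    or = paste0(ast_deparse(ast$lhs, 1L), " | ", ast_deparse(ast$rhs, 1L))
  )
  prec <- switch(ast$op, var = , const = 4L, not = 3L, and = 2L, or = 1L)
  if (prec < parent_prec) paste0("(", out, ")") else out
}

# ---- Tokenizer / recursive-descent parser -----------------------------------

.token_rx <- "[A-Za-z_][A-Za-z0-9_.]*|[01]|[()!&|]|\\S"

tokenize_expr <- function(s, where = "") {
  toks <- regmatches(s, gregexpr(.token_rx, s))[[1]]
  out <- vector("list", length(toks))
  for (k in seq_along(toks)) {
    tk <- toks[k]
    lower <- tolower(tk)
    out[[k]] <-
      if (tk %in% c("&", "|", "!", "(", ")")) {
        list(type = tk)
      } else if (lower == "and") {
        list(type = "&")
      } else if (lower == "or") {
        list(type = "|")
      } else if (lower == "not") {
        list(type = "!")
      } else if (tk %in% c("0", "1")) {
        list(type = "const", value = tk == "1")
      } else if (lower %in% c("true", "false")) {
        list(type = "const", value = lower == "true")
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_.]*$", tk)) {
        list(type = "var", name = tk)
      } else {
        stop("unexpected character '", tk, "'", where, call. = FALSE)
      }
  }
  out
}

#' Parse a single Boolean rule expression
#'
#' Grammar: `expr := term ('|' term)*`, `term := factor ('&' factor)*`,
#' `factor := '!' factor | '(' expr ')' | identifier | 0 | 1`.
#' Operator words `AND`, `OR`, `NOT` (any case) are synonyms for `&`, `|`, `!`.
#'
#' @param s expression text
#' @param where optional context string used in error messages
#' @return an expression tree (see internals)
#' @keywords internal
parse_expression <- function(s, where = "") {
  toks <- tokenize_expr(s, where)
  if (length(toks) == 0L) stop("empty rule expression", where, call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else NA_character_
  advance <- function() {
    tk <- toks[[pos]]
    pos <<- pos + 1L
    tk
  }
  parse_factor <- function() {
    tp <- peek()
    if (is.na(tp)) stop("unexpected end of rule", where, call. = FALSE)
    if (tp == "!") {
      advance()
      return(ast_not(parse_factor()))
    }
    if (tp == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) {
        stop("missing closing parenthesis", where, call. = FALSE)
      }
      advance()
      return(e)
    }
    if (tp == "var") {
      return(ast_var(advance()$name))
    }
    if (tp == "const") {
      return(ast_const(advance()$value))
    }
    stop("unexpected token '", tp, "'", where, call. = FALSE)
  }
  parse_and <- function() {
    e <- parse_factor()
    while (identical(peek(), "&")) {
      advance()
      e <- ast_and(e, parse_factor())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (identical(peek(), "|")) {
      advance()
      e <- ast_or(e, parse_and())
    }
    e
  }
  e <- parse_or()
  if (!is.na(peek())) {
    stop("trailing tokens after rule expression", where, call. = FALSE)
  }
  e
}

# ---- BooleanNetwork ----------------------------------------------------------

#' Construct a Boolean network from node names and rule expression trees
#'
#' Node order is significant: it fixes the column order of every state matrix
#' and the bit order of the exact oracle's state encoding.
#'
#' @param nodes character vector of unique node identifiers
#' @param rules list of expression trees, one per node, referencing only
#'   declared identifiers
#' @return an object of class `boolean_network` with elements `nodes`,
#'   `rules` (ASTs), `exprs` (compiled update calls), and `N`
#' @export
boolean_network <- function(nodes, rules) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
      paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(rules) != length(nodes)) {
    stop("need exactly one rule per node", call. = FALSE)
  }
  index <- stats::setNames(seq_along(nodes), nodes)
  for (j in seq_along(rules)) {
    bad <- setdiff(ast_vars(rules[[j]]), nodes)
    if (length(bad)) {
      stop("rule for '", nodes[j], "' references undeclared identifier(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      nodes = nodes,
      rules = rules,
      exprs = lapply(rules, compile_ast, index = index),
      N = length(nodes)
    ),
    class = "boolean_network"
  )
}

#' Parse a plain-text Boolean network rule file
#'
#' One rule per non-comment line, either `target, expression` (BNet style) or
#' `target = expression`.  Operators `&`, `|`, `!` and the words `AND`, `OR`,
#' `NOT` (case-insensitive) are accepted, as are parentheses and the literals
#' `0`/`1`.  Lines starting with `#` are comments; an optional
#' `targets, factors` header line is skipped.  Declaration order is preserved
#' and defines the node order of the returned network.
#'
#' @param text either the rule-file content as a single string (or character
#'   vector of lines), or a path to a file when `is_path = TRUE`
#' @param is_path interpret `text` as a file path
#' @return a [boolean_network()]
#' @examples
#' net <- parse_network("A, !B\nB, !A")
#' net$nodes
#' @export
parse_network <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty rule file", call. = FALSE)
  nodes <- character(0)
  rules <- list()
  first <- TRUE
  for (i in keep) {
    ln <- trimws(lines[i])
    if (first && grepl("^targets\\s*,\\s*factors$", ln, ignore.case = TRUE)) {
      first <- FALSE
      next
    }
    first <- FALSE
    m <- regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*(?:,|=)\\s*(.+)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L) {
      stop("cannot parse rule on line ", i, ": '", ln, "'", call. = FALSE)
    }
    target <- parts[2]
    if (target %in% nodes) {
      stop("duplicate target '", target, "' on line ", i, call. = FALSE)
    }
    nodes <- c(nodes, target)
    rules[[length(rules) + 1L]] <- parse_expression(
      parts[3],
      where = paste0(" (line ", i, ", target '", target, "')")
    )
  }
  # name undeclared identifiers together with the offending line
  for (j in seq_along(rules)) {
    bad <- setdiff(ast_vars(rules[[j]]), nodes)
    if (length(bad)) {
      stop("rule for '", nodes[j], "' (line ", keep[j],
        ") references undeclared identifier(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  boolean_network(nodes, rules)
}

#' Serialize a Boolean network to its canonical rule-file form
#'
#' @param net a [boolean_network()]
#' @param file optional path; when given the text is written there
#' @return the rule-file content, invisibly when writing to a file
#' @export
format_network <- function(net, file = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  txt <- paste0(
    vapply(
      seq_len(net$N),
      function(j) paste0(net$nodes[j], ", ", ast_deparse(net$rules[[j]])),
      character(1)
    ),
    collapse = "\n"
  )
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", x$N, "node(s)\n")
  cls <- tryCatch(classify_nodes(x), error = function(e) NULL)
  for (j in seq_len(x$N)) {
    tag <- if (is.null(cls)) "" else paste0("  [", cls[j], "]")
    cat(" ", x$nodes[j], "* = ", ast_deparse(x$rules[[j]]), tag, "\n", sep = "")
  }
  invisible(x)
}

# Evaluate rule j of `net` on a list of logical state columns.
eval_rule <- function(net, j, cols) {
  eval(net$exprs[[j]], list(.s = cols))
}
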