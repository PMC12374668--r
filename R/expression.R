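# Boolean gate expressions. The grammar accepts both functional and infix
# syntax, case-insensitively:
#
#   expr    := or_expr
#   or_expr := and_expr ( "OR" and_expr )*
#   and_expr:= unary ( "AND" unary )*
#   unary   := ("NOT" | "YES") unary | primary
#   primary := op "(" expr ("," expr)* ")" | name | "(" expr ")"
#   op      := "YES" | "NOT" | "AND" | "OR"
#
# so "AND(InA, InB)", "InA AND InB" and "YES(InA) AND YES(InB)" all parse to
# the same tree. Nodes are lists: list(op = "VAR", name = ...) or
# list(op = "AND"/"OR"/"NOT", args = list(...)).

#' @noRd
tokenize_expression <- function(text) {
  pat <- "\\s*([A-Za-z_][A-Za-z0-9_]*|\\(|\\)|,)"
  tokens <- character(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substr(text, pos, n), perl = TRUE)
    if (m != 1L) {
      rlang::abort(sprintf(
        "parse error at position %d: unexpected character '%s'",
        pos, substr(text, pos, pos)
      ), class = "dt_parse_error")
    }
    len <- attr(m, "match.length")
    tok <- trimws(substr(text, pos, pos + len - 1L))
    tokens <- c(tokens, tok)
    pos <- pos + len
  }
  tokens
}

#' Parse a Boolean gate expression
#'
#' @param text Expression string over named inputs using `YES`, `NOT`,
#'   `AND`, `OR` (functional or infix form), or an already-parsed node
#'   (returned unchanged).
#' @return An expression tree (nested lists with fields `op` and
#'   `args`/`name`).
#' @export
#' @examples
#' parse_expression("AND(InA, NOT(InB))")
#' parse_expression("InA OR InB")
parse_expression <- function(text) {
  if (is.list(text) && !is.null(text$op)) {
    return(text)
  }
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    rlang::abort("expression must be a non-empty string", class = "dt_parse_error")
  }
  tokens <- tokenize_expression(text)
  i <- 1L
  peek <- function() if (i <= length(tokens)) tokens[i] else NA_character_
  advance <- function() {
    t <- peek()
    i <<- i + 1L
    t
  }
  expect <- function(tok) {
    t <- advance()
    if (is.na(t) || t != tok) {
      rlang::abort(sprintf(
        "parse error at token %d: expected '%s', got '%s'",
        i - 1L, tok, ifelse(is.na(t), "<end>", t)
      ), class = "dt_parse_error")
    }
  }
  is_op <- function(t, op) !is.na(t) && toupper(t) == op

  parse_or <- function() {
    node <- parse_and()
    while (is_op(peek(), "OR")) {
      advance()
      node <- list(op = "OR", args = list(node, parse_and()))
    }
    node
  }
  parse_and <- function() {
    node <- parse_unary()
    while (is_op(peek(), "AND")) {
      advance()
      node <- list(op = "AND", args = list(node, parse_unary()))
    }
    node
  }
  parse_unary <- function() {
    t <- peek()
    if (is_op(t, "NOT") || is_op(t, "YES")) {
      # only prefix form when not followed by "(" (else functional form)
      if (!identical(tokens[i + 1L], "(")) {
        advance()
        inner <- parse_unary()
        if (toupper(t) == "NOT") {
          return(list(op = "NOT", args = list(inner)))
        }
        return(inner)
      }
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- advance()
    if (is.na(t)) {
      rlang::abort("parse error: unexpected end of expression",
        class = "dt_parse_error"
      )
    }
    if (t == "(") {
      node <- parse_or()
      expect(")")
      return(node)
    }
    up <- toupper(t)
    if (up %in% c("YES", "NOT", "AND", "OR") && identical(peek(), "(")) {
      advance()
      args <- list(parse_or())
      while (identical(peek(), ",")) {
        advance()
        args <- c(args, list(parse_or()))
      }
      expect(")")
      if (up == "YES") {
        if (length(args) != 1L) {
          rlang::abort("YES takes exactly one argument", class = "dt_parse_error")
        }
        return(args[[1]])
      }
      if (up == "NOT") {
        if (length(args) != 1L) {
          rlang::abort("NOT takes exactly one argument", class = "dt_parse_error")
        }
        return(list(op = "NOT", args = args))
      }
      if (length(args) < 2L) {
        rlang::abort(sprintf("%s needs at least two arguments", up),
          class = "dt_parse_error"
        )
      }
      return(list(op = up, args = args))
    }
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", t)) {
      return(list(op = "VAR", name = t))
    }
    rlang::abort(sprintf("parse error at token %d: '%s'", i - 1L, t),
      class = "dt_parse_error"
    )
  }

  node <- parse_or()
  if (!is.na(peek())) {
    rlang::abort(sprintf(
      "parse error at token %d: trailing input '%s'", i, peek()
    ), class = "dt_parse_error")
  }
  node
}

#' Input names referenced by an expression
#' @param expr Expression string or parsed node.
#' @return Character vector of distinct input names, in first-use order.
#' @export
expr_inputs <- function(expr) {
  node <- parse_expression(expr)
  walk <- function(n) {
    if (n$op == "VAR") {
      return(n$name)
    }
    unlist(lapply(n$args, walk))
  }
  unique(walk(node))
}

#' Evaluate an expression on a truth assignment
#' @param expr Expression string or parsed node.
#' @param assignment Named logical vector mapping input names to presence.
#' @return Logical scalar.
#' @export
#' @examples
#' eval_expression("AND(a, NOT(b))", c(a = TRUE, b = FALSE))
eval_expression <- function(expr, assignment) {
  node <- parse_expression(expr)
  ev <- function(n) {
    switch(n$op,
      VAR = {
        if (!n$name %in% names(assignment)) {
          rlang::abort(sprintf("no assignment for input '%s'", n$name))
        }
        isTRUE(assignment[[n$name]])
      },
      NOT = !ev(n$args[[1]]),
      AND = all(vapply(n$args, ev, logical(1))),
      OR = any(vapply(n$args, ev, logical(1)))
    )
  }
  ev(node)
}

#' Render an expression node back to canonical functional syntax
#' @param expr Expression string or parsed node.
#' @return A string.
#' @export
expr_to_string <- function(expr) {
  node <- parse_expression(expr)
  render <- function(n) {
    switch(n$op,
      VAR = n$name,
      NOT = paste0("NOT(", render(n$args[[1]]), ")"),
      paste0(n$op, "(", paste(vapply(n$args, render, character(1)),
        collapse = ", "
      ), ")")
    )
  }
  render(node)
}

# ---- normalization to the single-particle architecture plan ----------------
#
# The disassembly architecture realizes gate functions of the product form
#
#     f  =  (AND over shield conditions G_i)  AND  (OR over marker terms)
#
# where each shield condition G_i is a positive gate realizable on one
# severable core/shield bridge (a literal, an OR chain, or a cooperative AND
# junction, fan-in <= 4) and each marker term is NOT(H_j) for such a gate H_j
# (marker strands released when H_j fires). Expressions outside this class
# (e.g. `x OR NOT y`) would need mixtures of particle species and are
# rejected.

#' @noRd
simplify_node <- function(n) {
  if (n$op == "VAR") {
    return(n)
  }
  n$args <- lapply(n$args, simplify_node)
  if (n$op == "NOT" && n$args[[1]]$op == "NOT") {
    return(n$args[[1]]$args[[1]])
  }
  if (n$op %in% c("AND", "OR")) {
    # flatten same-op children
    flat <- list()
    for (a in n$args) {
      if (a$op == n$op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
    }
    # dedupe identical literal children
    keys <- vapply(flat, expr_to_string, character(1))
    flat <- flat[!duplicated(keys)]
    if (length(flat) == 1L) {
      return(flat[[1]])
    }
    n$args <- flat
  }
  n
}

# A "condition": positive gate realizable on one severable core/shield
# bridge, expressed in disjunctive normal form over distinct inputs. Each
# OR term becomes one junction of a staple chain; a multi-input term
# becomes a cooperatively partitioned junction. Returns
# list(terms = list(character vectors), inputs = character vector) or NULL
# if the node is not such a gate.
#' @noRd
node_condition <- function(n) {
  term_of <- function(m) {
    if (m$op == "VAR") {
      return(m$name)
    }
    if (m$op == "AND" &&
      all(vapply(m$args, function(a) a$op == "VAR", logical(1)))) {
      return(unique(vapply(m$args, function(a) a$name, character(1))))
    }
    NULL
  }
  terms <- NULL
  if (n$op == "OR") {
    terms <- lapply(n$args, term_of)
    if (any(vapply(terms, is.null, logical(1)))) {
      return(NULL)
    }
  } else {
    t1 <- term_of(n)
    if (is.null(t1)) {
      return(NULL)
    }
    terms <- list(t1)
  }
  inputs <- unlist(terms)
  if (anyDuplicated(inputs)) {
    # an input drives exactly one invasion site; reuse across junctions
    # would require duplicated complementary receptors (cross-talk)
    return(NULL)
  }
  check_condition_fanin(terms, inputs)
  list(terms = terms, inputs = inputs)
}

#' @noRd
check_condition_fanin <- function(terms, inputs) {
  if (length(inputs) > 4L || any(lengths(terms) > 4L)) {
    rlang::abort(sprintf(
      "unsupported fan-in: bridge condition over %d inputs exceeds the 4-input-per-staple ceiling",
      length(inputs)
    ), class = "dt_unsupported_fanin")
  }
  invisible(terms)
}

#' @noRd
unrealizable_error <- function(node) {
  rlang::abort(
    sprintf(
      paste0(
        "expression '%s' is not realizable on a single-particle ",
        "disassembly architecture (supported: AND of positive YES/OR/AND ",
        "bridge conditions with an optional disjunction of NOT terms; ",
        "mixed clauses such as 'x OR NOT y' require multi-particle mixtures)"
      ),
      expr_to_string(node)
    ),
    class = "dt_unrealizable_expression"
  )
}

# Normalize an expression into the architecture plan:
# list(shields = list of conditions, markers = list of conditions (negated),
#      constitutive_marker = logical)
#' @noRd
normalize_expression <- function(expr) {
  node <- simplify_node(parse_expression(expr))

  as_marker_condition <- function(not_node) {
    cond <- node_condition(not_node$args[[1]])
    if (is.null(cond)) unrealizable_error(not_node)
    cond
  }
  finalize <- function(plan) {
    all_inputs <- unlist(lapply(c(plan$shields, plan$markers), `[[`, "inputs"))
    if (anyDuplicated(all_inputs)) {
      rlang::abort(
        sprintf(
          "expression '%s' reuses an input across bridges; each input drives exactly one invasion site",
          expr_to_string(node)
        ),
        class = "dt_unrealizable_expression"
      )
    }
    plan
  }

  if (node$op == "NOT") {
    return(finalize(list(
      shields = list(), markers = list(as_marker_condition(node)),
      constitutive_marker = FALSE
    )))
  }
  cond <- node_condition(node)
  if (!is.null(cond)) {
    return(finalize(list(
      shields = list(cond), markers = list(),
      constitutive_marker = TRUE
    )))
  }
  if (node$op == "OR") {
    # either all children are NOT(condition) -> marker disjunction,
    # or the node would need mixtures
    if (all(vapply(node$args, function(a) a$op == "NOT", logical(1)))) {
      return(finalize(list(
        shields = list(),
        markers = lapply(node$args, as_marker_condition),
        constitutive_marker = FALSE
      )))
    }
    unrealizable_error(node)
  }
  if (node$op == "AND") {
    shields <- list()
    not_children <- list()
    marker_or <- NULL
    for (a in node$args) {
      c_a <- node_condition(a)
      if (!is.null(c_a)) {
        shields <- c(shields, list(c_a))
      } else if (a$op == "NOT") {
        not_children <- c(not_children, list(a$args[[1]]))
      } else if (a$op == "OR" &&
        all(vapply(a$args, function(x) x$op == "NOT", logical(1)))) {
        if (!is.null(marker_or)) unrealizable_error(node)
        marker_or <- lapply(a$args, as_marker_condition)
      } else {
        unrealizable_error(node)
      }
    }
    markers <- list()
    if (length(not_children) > 0L) {
      # AND of NOTs: NOT(a) AND NOT(b) == NOT(OR(a, b)) -> one marker whose
      # release condition is the OR of the negated sub-conditions (a chain
      # of severable junctions on the marker's anchoring bridge)
      merged <- if (length(not_children) == 1L) {
        not_children[[1]]
      } else {
        simplify_node(list(op = "OR", args = not_children))
      }
      cond_m <- node_condition(merged)
      if (is.null(cond_m)) unrealizable_error(node)
      markers <- list(cond_m)
    }
    if (!is.null(marker_or)) {
      if (length(markers) > 0L) unrealizable_error(node)
      markers <- marker_or
    }
    if (length(shields) == 0L && length(markers) == 0L) unrealizable_error(node)
    return(finalize(list(
      shields = shields, markers = markers,
      constitutive_marker = length(markers) == 0L
    )))
  }
  unrealizable_error(node)
}
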