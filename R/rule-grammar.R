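#' @useDynLib tcellsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Boolean rule grammar
##
## Concrete syntax for node update rules:
##   expr    := term ('|' term)*          OR, lowest precedence
##   term    := factor ('&' factor)*      AND
##   factor  := '!' factor | '(' expr ')' | identifier
## Identifiers: [A-Za-z_][A-Za-z0-9_.]*

rule_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else if (ch %in% c("!", "&", "|", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[[j]])) j <- j + 1L
      tokens[[length(tokens) + 1L]] <- list(
        type = "ident",
        value = paste(chars[i:(j - 1L)], collapse = ""),
        pos = i
      )
      i <- j
    } else {
      stop(sprintf("rule syntax error: unexpected character '%s' at position %d",
                   ch, i), call. = FALSE)
    }
  }
  tokens
}

#' Parse a Boolean rule expression
#'
#' Parses the plain-text rule grammar (`!` NOT, `&` AND, `|` OR, parentheses;
#' `!` binds tightest, `|` loosest) into an expression tree.
#'
#' @param text A single non-empty rule string, e.g. `"A & !B"`.
#' @return An object of class `logic_rule` with elements `expr` (the
#'   expression tree) and `regulators` (referenced node names, in order of
#'   first appearance).
#' @examples
#' r <- parse_rule("A | (B & !C)")
#' r$regulators
#' @export
parse_rule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("rule text must be a single string", call. = FALSE)
  }
  if (!nzchar(trimws(text))) {
    stop("empty rule expression", call. = FALSE)
  }
  tokens <- rule_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1L

  peek <- function() {
    if (state$i <= length(state$tokens)) state$tokens[[state$i]] else NULL
  }
  advance <- function() {
    tok <- peek()
    state$i <- state$i + 1L
    tok
  }
  fail <- function(tok, what) {
    pos <- if (is.null(tok)) nchar(text) + 1L else tok$pos
    stop(sprintf("rule syntax error: %s at position %d in \"%s\"",
                 what, pos, text), call. = FALSE)
  }

  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      node <- list(type = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      node <- list(type = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "unexpected end of expression")
    if (tok$type == "!") {
      advance()
      return(list(type = "not", arg = parse_factor()))
    }
    if (tok$type == "(") {
      advance()
      node <- parse_expr()
      close <- peek()
      if (is.null(close) || close$type != ")") fail(close, "expected ')'")
      advance()
      return(node)
    }
    if (tok$type == "ident") {
      advance()
      return(list(type = "var", name = tok$value))
    }
    fail(tok, sprintf("unexpected '%s'", tok$type))
  }

  expr <- parse_expr()
  leftover <- peek()
  if (!is.null(leftover)) {
    fail(leftover, sprintf("unexpected '%s'",
                           if (leftover$type == "ident") leftover$value
                           else leftover$type))
  }
  new_logic_rule(expr)
}

new_logic_rule <- function(expr) {
  structure(
    list(expr = expr, regulators = collect_regulators(expr)),
    class = "logic_rule"
  )
}

collect_regulators <- function(expr) {
  out <- character(0)
  walk <- function(node) {
    switch(node$type,
      var = out[[length(out) + 1L]] <<- node$name,
      not = walk(node$arg),
      and = { walk(node$lhs); walk(node$rhs) },
      or  = { walk(node$lhs); walk(node$rhs) },
      stop("malformed expression tree", call. = FALSE)
    )
  }
  walk(expr)
  unique(out)
}

rule_precedence <- c(or = 1L, and = 2L, not = 3L, var = 4L)

#' Render a rule back to its text form
#'
#' Inverse of [parse_rule()]: the returned string parses back to an identical
#' expression tree, with parentheses only where precedence requires them.
#'
#' @param rule A `logic_rule`.
#' @return A single string.
#' @export
format_rule <- function(rule) {
  stopifnot(inherits(rule, "logic_rule"))
  render <- function(node, parent_prec) {
    txt <- switch(node$type,
      var = node$name,
      not = paste0("!", render(node$arg, rule_precedence[["not"]])),
      and = paste(render(node$lhs, rule_precedence[["and"]]), "&",
                  render(node$rhs, rule_precedence[["and"]] + 1L)),
      or  = paste(render(node$lhs, rule_precedence[["or"]]), "|",
                  render(node$rhs, rule_precedence[["or"]] + 1L))
    )
    if (rule_precedence[[node$type]] < parent_prec) paste0("(", txt, ")") else txt
  }
  render(rule$expr, 0L)
}

#' @export
print.logic_rule <- function(x, ...) {
  cat("<logic_rule> ", format_rule(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a rule on a Boolean state
#'
#' @param rule A `logic_rule`.
#' @param state Named vector (0/1 or logical) assigning a value to every
#'   regulator of the rule.
#' @return 0 or 1.
#' @export
evaluate_rule <- function(rule, state) {
  stopifnot(inherits(rule, "logic_rule"))
  missing <- setdiff(rule$regulators, names(state))
  if (length(missing) > 0L) {
    stop(sprintf("state is missing regulator(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vals <- state[rule$regulators]
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("state values must be 0/1", call. = FALSE)
  }
  as.integer(eval_expr_vec(rule$expr,
                           lapply(as.list(vals), as.logical)))
}

## Vectorized evaluation: `bindings` is a named list of logical vectors of
## equal length; returns a logical vector.
eval_expr_vec <- function(expr, bindings) {
  switch(expr$type,
    var = bindings[[expr$name]],
    not = !eval_expr_vec(expr$arg, bindings),
    and = eval_expr_vec(expr$lhs, bindings) & eval_expr_vec(expr$rhs, bindings),
    or  = eval_expr_vec(expr$lhs, bindings) | eval_expr_vec(expr$rhs, bindings)
  )
}

#' Full truth table of a rule
#'
#' Enumerates all `2^k` assignments of the rule's `k` regulators. Assignment
#' `i` (0-based) sets regulator `j` to bit `j - 1` of `i`, i.e. the first
#' regulator is the least significant bit.
#'
#' @param rule A `logic_rule`.
#' @param max_regulators Guard against enumerating huge tables.
#' @return Integer vector of length `2^k` of 0/1 outputs.
#' @export
rule_truth_table <- function(rule, max_regulators = 16L) {
  stopifnot(inherits(rule, "logic_rule"))
  regs <- rule$regulators
  k <- length(regs)
  if (k > max_regulators) {
    stop(sprintf("rule has %d regulators; truth-table enumeration capped at %d",
                 k, max_regulators), call. = FALSE)
  }
  n_rows <- 2L^k
  idx <- seq_len(n_rows) - 1L
  bindings <- list()
  for (j in seq_len(k)) {
    bindings[[regs[[j]]]] <- bitwAnd(idx %/% 2L^(j - 1L), 1L) == 1L
  }
  if (k == 0L) bindings <- list()
  as.integer(eval_expr_vec(rule$expr, bindings))
}
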