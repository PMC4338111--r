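#' Boolean criterion expressions over dataset columns
#'
#' A criterion selects the rows of interest in an omics dataset — e.g. the
#' differentially expressed genes via `ABS([log2FC]) > 1 AND [pvalue] <
#' 0.05`.  The language has bracketed column references, numeric and quoted
#' string literals, the comparisons `<  <=  >  >=  =  <>`, the boolean
#' connectives `AND`, `OR`, `NOT` (precedence: comparison, then `NOT`, then
#' `AND`, then `OR`; left-associative; parentheses override) and one
#' built-in function, `ABS()`.  Evaluation is three-valued: any comparison
#' touching a missing value is undefined (`NA`), and the connectives
#' propagate undefined by Kleene logic (`FALSE AND NA` is `FALSE`, `TRUE OR
#' NA` is `TRUE`).  A row "meets the criterion" only when the result is
#' exactly `TRUE`.
#'
#' String values support only `=` and `<>`; comparing a string with an
#' order operator, or a string with a number, is an evaluation error naming
#' the offending column.
#'
#' @param text Criterion source text.
#' @return `parse_criterion()` returns an object of class `criterion`
#'   holding the source text and the parsed expression tree; a syntax error
#'   aborts with the 1-based character position.
#' @examples
#' cr <- parse_criterion("ABS([log2FC]) > 1 AND [pvalue] < 0.05")
#' evaluate_criterion(cr, list(log2FC = 1.5, pvalue = 0.01))
#' evaluate_criterion(cr, list(log2FC = NA, pvalue = 0.01))  # undefined
#' @export
parse_criterion <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    abort("criterion text must be a non-empty string")
  }
  toks <- tokenize_criterion(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$text <- text
  ast <- parse_or(st)
  tk <- peek(st)
  if (tk$type != "eof") {
    syntax_error(st, tk, sprintf("unexpected '%s'", tk$value))
  }
  structure(list(source_text = text, ast = ast), class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cat("<criterion>", x$source_text, "\n")
  invisible(x)
}

#' @export
format.criterion <- function(x, ...) deparse_criterion(x$ast)

## ---- tokenizer -------------------------------------------------------------

TOKEN_PATTERNS <- list(
  c("ws",     "^\\s+"),
  c("col",    "^\\[([^\\]]*)\\]"),
  c("number", "^[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"),
  c("string", "^(?:\"[^\"]*\"|'[^']*')"),
  c("op",     "^(?:<=|>=|<>|<|>|=)"),
  c("lparen", "^\\("),
  c("rparen", "^\\)"),
  c("word",   "^[A-Za-z_][A-Za-z0-9_]*"))

tokenize_criterion <- function(text) {
  toks <- list(); pos <- 1L; rest <- text
  while (nzchar(rest)) {
    matched <- FALSE
    for (tp in TOKEN_PATTERNS) {
      m <- regmatches(rest, regexpr(tp[2], rest, perl = TRUE))
      if (length(m)) {
        if (tp[1] != "ws") {
          toks[[length(toks) + 1L]] <- list(type = tp[1], value = m, pos = pos)
        }
        pos <- pos + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      abort(sprintf("syntax error at position %d: unexpected character '%s'",
                    pos, substring(rest, 1, 1)))
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", value = "", pos = pos)
  toks
}

peek <- function(st) st$toks[[st$i]]
advance <- function(st) { tk <- st$toks[[st$i]]; st$i <- st$i + 1L; tk }

syntax_error <- function(st, tk, what) {
  abort(sprintf("syntax error at position %d: %s", tk$pos, what))
}

is_keyword <- function(tk, kw) {
  tk$type == "word" && toupper(tk$value) == kw
}

## ---- recursive-descent parser ---------------------------------------------
## or := and (OR and)* ; and := not (AND not)* ; not := NOT not | primary
## primary := '(' or ')' | value cmp value
## value := number | string | [col] | ABS '(' value ')'

ast_node <- function(op, ...) c(list(op = op), list(...))

parse_or <- function(st) {
  left <- parse_and(st)
  while (is_keyword(peek(st), "OR")) {
    advance(st)
    left <- ast_node("or", lhs = left, rhs = parse_and(st))
  }
  left
}

parse_and <- function(st) {
  left <- parse_not(st)
  while (is_keyword(peek(st), "AND")) {
    advance(st)
    left <- ast_node("and", lhs = left, rhs = parse_not(st))
  }
  left
}

parse_not <- function(st) {
  if (is_keyword(peek(st), "NOT")) {
    advance(st)
    return(ast_node("not", arg = parse_not(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  tk <- peek(st)
  if (tk$type == "lparen") {
    advance(st)
    inner <- parse_or(st)
    tk2 <- peek(st)
    if (tk2$type != "rparen") syntax_error(st, tk2, "expected ')'")
    advance(st)
    return(inner)
  }
  lhs <- parse_value(st)
  tk <- peek(st)
  if (tk$type != "op") {
    syntax_error(st, tk, if (tk$type == "eof") "expected a comparison operator, got end of input"
                 else sprintf("expected a comparison operator, got '%s'", tk$value))
  }
  op <- advance(st)$value
  rhs <- parse_value(st)
  ast_node("cmp", cmp = op, lhs = lhs, rhs = rhs)
}

parse_value <- function(st) {
  tk <- peek(st)
  if (tk$type == "number") {
    advance(st)
    return(ast_node("num", value = as.numeric(tk$value)))
  }
  if (tk$type == "string") {
    advance(st)
    return(ast_node("str", value = substring(tk$value, 2L, nchar(tk$value) - 1L)))
  }
  if (tk$type == "col") {
    advance(st)
    name <- sub("^\\[", "", sub("\\]$", "", tk$value))
    if (!nzchar(name)) syntax_error(st, tk, "empty column reference '[]'")
    return(ast_node("col", name = name))
  }
  if (tk$type == "word") {
    if (toupper(tk$value) == "ABS") {
      advance(st)
      tk2 <- peek(st)
      if (tk2$type != "lparen") syntax_error(st, tk2, "expected '(' after ABS")
      advance(st)
      arg <- parse_value(st)
      tk3 <- peek(st)
      if (tk3$type != "rparen") syntax_error(st, tk3, "expected ')'")
      advance(st)
      return(ast_node("abs", arg = arg))
    }
    if (st$i < length(st$toks) && st$toks[[st$i + 1L]]$type == "lparen") {
      abort(sprintf("unknown function '%s' at position %d (only ABS is available)",
                    tk$value, tk$pos))
    }
  }
  syntax_error(st, tk, if (tk$type == "eof") "expected a value, got end of input"
               else sprintf("expected a value, got '%s'", tk$value))
}

## ---- pretty printer --------------------------------------------------------

# Fully parenthesized canonical form; reparsing it yields an identical tree.
deparse_criterion <- function(node) {
  switch(node$op,
    or  = sprintf("(%s OR %s)", deparse_criterion(node$lhs),
                  deparse_criterion(node$rhs)),
    and = sprintf("(%s AND %s)", deparse_criterion(node$lhs),
                  deparse_criterion(node$rhs)),
    not = sprintf("(NOT %s)", deparse_criterion(node$arg)),
    cmp = sprintf("%s %s %s", deparse_criterion(node$lhs), node$cmp,
                  deparse_criterion(node$rhs)),
    abs = sprintf("ABS(%s)", deparse_criterion(node$arg)),
    num = fmt_num(node$value),
    str = sprintf("\"%s\"", node$value),
    col = sprintf("[%s]", node$name),
    abort(sprintf("internal: unknown AST node '%s'", node$op)))
}

## ---- evaluation ------------------------------------------------------------

# Vectorized evaluation over an environment of parallel column vectors.
# Boolean results are logical vectors where NA encodes "undefined"; R's NA
# semantics for & | ! are exactly Kleene three-valued logic.
eval_value <- function(node, env, n) {
  switch(node$op,
    num = rep(node$value, n),
    str = rep(node$value, n),
    col = {
      if (!node$name %in% names(env)) {
        abort(sprintf("unknown column '%s' in criterion", node$name))
      }
      env[[node$name]]
    },
    abs = {
      v <- eval_value(node$arg, env, n)
      if (is.character(v)) {
        abort(sprintf("ABS() applied to non-numeric value%s",
                      col_hint(node$arg)))
      }
      abs(v)
    },
    abort(sprintf("expected a value, got boolean expression '%s'", node$op)))
}

col_hint <- function(node) {
  if (identical(node$op, "col")) sprintf(" (column '%s')", node$name) else ""
}

eval_bool <- function(node, env, n) {
  switch(node$op,
    and = eval_bool(node$lhs, env, n) & eval_bool(node$rhs, env, n),
    or  = eval_bool(node$lhs, env, n) | eval_bool(node$rhs, env, n),
    not = !eval_bool(node$arg, env, n),
    cmp = {
      l <- eval_value(node$lhs, env, n)
      r <- eval_value(node$rhs, env, n)
      lc <- is.character(l); rc <- is.character(r)
      if (lc != rc) {
        abort(sprintf("type mismatch in comparison%s%s: string vs number",
                      col_hint(node$lhs), col_hint(node$rhs)))
      }
      if (lc && !node$cmp %in% c("=", "<>")) {
        abort(sprintf("operator '%s' is not defined for strings%s%s",
                      node$cmp, col_hint(node$lhs), col_hint(node$rhs)))
      }
      switch(node$cmp,
        "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r,
        "=" = l == r, "<>" = l != r)
    },
    abort(sprintf("expected a boolean expression, got a bare value")))
}

#' @rdname parse_criterion
#' @param criterion A `criterion` (from `parse_criterion()`) or its source
#'   text.
#' @param row A named list or one-row data frame of column values; missing
#'   values are `NA`.
#' @return `evaluate_criterion()` returns `TRUE`, `FALSE` or `NA`
#'   (undefined).
#' @export
evaluate_criterion <- function(criterion, row) {
  criterion <- as_criterion(criterion)
  env <- lapply(as.list(row), function(v) {
    if (is.factor(v)) v <- as.character(v)
    v
  })
  res <- eval_bool(criterion$ast, env, 1L)
  as.logical(res[1L])
}

as_criterion <- function(x) {
  if (inherits(x, "criterion")) x else parse_criterion(x)
}

# Evaluate a criterion down the rows of a dataset; returns a logical vector
# (NA = undefined) of length nrow.
eval_criterion_rows <- function(criterion, data) {
  criterion <- as_criterion(criterion)
  n <- nrow(data)
  if (n == 0L) return(logical())
  res <- eval_bool(criterion$ast, as.list(data), n)
  rep_len(as.logical(res), n)
}
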