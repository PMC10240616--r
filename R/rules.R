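# Boolean rule expressions: parsing, evaluation, fuzzification.
#
# Expression trees are nested lists with an `op` field:
#   list(op = "var",   name = <node name>)
#   list(op = "const", value = 0 or 1)
#   list(op = "not",   arg = <expr>)
#   list(op = "and"/"or", lhs = <expr>, rhs = <expr>)
# AND/OR are parsed left-associatively; NOT binds tightest.

#' Tokenize a rule string
#'
#' @param text rule string.
#' @return data.frame with columns `token` and `pos` (1-based token index).
#' @noRd
tokenize_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # split on parentheses and whitespace, keeping parentheses
  raw <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(raw), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    stop("rule syntax error: empty rule", call. = FALSE)
  }
  bad <- grep("^[A-Za-z0-9_()]+$", toks, invert = TRUE)
  if (length(bad)) {
    stop(sprintf("rule syntax error at token %d: invalid token '%s'",
                 bad[1], toks[bad[1]]), call. = FALSE)
  }
  data.frame(token = toks, pos = seq_along(toks), stringsAsFactors = FALSE)
}

#' Parse a Boolean rule
#'
#' Parses an infix AND/OR/NOT expression over node names into an expression
#' tree. AND and OR are left-associative, NOT binds tightest, parentheses
#' group. The literal constants `0` and `1` are permitted.
#'
#' @param text rule string, e.g. `"STAT1 AND NOT SOCS1"`.
#' @param target optional name of the node this rule updates.
#' @return an object of class `boolean_rule` with fields `target` and `expr`.
#' @examples
#' r <- parse_rule("STAT1 AND NOT SOCS1")
#' deparse_rule(r)
#' @export
parse_rule <- function(text, target = NA_character_) {
  toks <- tokenize_rule(text)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$token[i] else NA_character_
  advance <- function() {
    t <- toks$token[i]
    i <<- i + 1L
    t
  }
  fail <- function(msg) {
    at <- if (i <= n) sprintf("token %d ('%s')", i, toks$token[i])
          else sprintf("end of input (token %d)", n + 1L)
    stop(sprintf("rule syntax error at %s: %s", at, msg), call. = FALSE)
  }
  is_keyword <- function(t) !is.na(t) && t %in% c("AND", "OR", "NOT")

  parse_expr <- function() {
    e <- parse_term()
    while (identical(peek(), "OR")) {
      advance()
      e <- list(op = "or", lhs = e, rhs = parse_term())
    }
    e
  }
  parse_term <- function() {
    e <- parse_factor()
    while (identical(peek(), "AND")) {
      advance()
      e <- list(op = "and", lhs = e, rhs = parse_factor())
    }
    e
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("expected operand")
    if (t == "NOT") {
      advance()
      return(list(op = "not", arg = parse_factor()))
    }
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(e)
    }
    if (t %in% c("AND", "OR", ")")) fail("expected operand")
    advance()
    if (t %in% c("0", "1")) return(list(op = "const", value = as.numeric(t)))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", t)) {
      stop(sprintf("rule syntax error at token %d ('%s'): not a valid node name",
                   i - 1L, t), call. = FALSE)
    }
    list(op = "var", name = t)
  }

  e <- parse_expr()
  if (i <= n) fail("unexpected trailing input")
  structure(list(target = target, expr = e), class = "boolean_rule")
}

#' Deparse a rule expression back to its text form
#'
#' Inverse of [parse_rule()] up to whitespace: round-tripping a parsed rule
#' reproduces an equivalent, fully parenthesized-where-needed expression.
#'
#' @param rule a `boolean_rule` or a bare expression tree.
#' @return single character string.
#' @export
deparse_rule <- function(rule) {
  e <- if (inherits(rule, "boolean_rule")) rule$expr else rule
  prec <- c(or = 1, and = 2, not = 3, var = 4, const = 4)
  dp <- function(e, parent_prec) {
    out <- switch(e$op,
      var   = e$name,
      const = as.character(e$value),
      not   = paste0("NOT ", dp(e$arg, prec[["not"]])),
      and   = paste0(dp(e$lhs, prec[["and"]]), " AND ",
                     dp(e$rhs, prec[["and"]] + 0.5)),
      or    = paste0(dp(e$lhs, prec[["or"]]), " OR ",
                     dp(e$rhs, prec[["or"]] + 0.5))
    )
    if (prec[[e$op]] < parent_prec) paste0("(", out, ")") else out
  }
  dp(e, 0)
}

#' @export
format.boolean_rule <- function(x, ...) {
  lhs <- if (is.na(x$target)) "" else paste0(x$target, " = ")
  paste0(lhs, deparse_rule(x))
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Names of the nodes referenced by a rule
#'
#' @param rule `boolean_rule` or expression tree.
#' @return character vector of distinct node names, in order of appearance.
#' @export
rule_inputs <- function(rule) {
  e <- if (inherits(rule, "boolean_rule")) rule$expr else rule
  acc <- character(0)
  walk <- function(e) {
    switch(e$op,
      var   = acc[[length(acc) + 1L]] <<- e$name,
      const = NULL,
      not   = walk(e$arg),
      { walk(e$lhs); walk(e$rhs) }  # and / or
    )
    invisible(NULL)
  }
  walk(e)
  unique(acc)
}

#' Interaction signs implied by a rule
#'
#' A source is a positive regulator of the rule's target if it occurs under an
#' even number of NOTs, negative if odd, and `"+-"` (mixed) if it has
#' occurrences of both parities.
#'
#' @param rule `boolean_rule` or expression tree.
#' @return data.frame with columns `source` and `sign` (`"+"`, `"-"`, `"+-"`).
#' @export
rule_signs <- function(rule) {
  e <- if (inherits(rule, "boolean_rule")) rule$expr else rule
  pos <- character(0); neg <- character(0)
  walk <- function(e, under_not) {
    switch(e$op,
      var = {
        if (under_not) neg[[length(neg) + 1L]] <<- e$name
        else pos[[length(pos) + 1L]] <<- e$name
      },
      const = NULL,
      not = walk(e$arg, !under_not),
      { walk(e$lhs, under_not); walk(e$rhs, under_not) }
    )
    invisible(NULL)
  }
  walk(e, FALSE)
  src <- unique(c(pos, neg))
  sign <- vapply(src, function(s) {
    p <- s %in% pos; m <- s %in% neg
    if (p && m) "+-" else if (m) "-" else "+"
  }, character(1))
  data.frame(source = src, sign = unname(sign), stringsAsFactors = FALSE)
}

#' Evaluate a rule as classical Boolean logic
#'
#' @param rule `boolean_rule` or expression tree.
#' @param state named vector (or list) of 0/1 (or logical) node values.
#'   Values may be vectors of common length, in which case the rule is
#'   evaluated elementwise.
#' @return 0/1 value(s) of the expression.
#' @export
boolean_evaluate <- function(rule, state) {
  e <- if (inherits(rule, "boolean_rule")) rule$expr else rule
  ev <- function(e) {
    switch(e$op,
      var = {
        v <- state[[e$name]]
        if (is.null(v)) stop(sprintf("missing value for node '%s'", e$name),
                             call. = FALSE)
        as.logical(v)
      },
      const = e$value == 1,
      not   = !ev(e$arg),
      and   = ev(e$lhs) & ev(e$rhs),
      or    = ev(e$lhs) | ev(e$rhs)
    )
  }
  as.numeric(ev(e))
}

#' Fuzzify a Boolean rule
#'
#' Structural recursion replacing the Boolean connectives with their
#' probabilistic counterparts: `q AND p -> q*p`, `q OR p -> q + p - q*p`,
#' `NOT p -> 1 - p`. On inputs in `[0,1]` the result lies in `[0,1]`, and on
#' Boolean-valued inputs it coincides with [boolean_evaluate()].
#'
#' @param rule `boolean_rule` or expression tree.
#' @return function of one argument (named numeric state vector or list)
#'   returning the fuzzy truth value of the expression.
#' @export
fuzzify_expression <- function(rule) {
  e <- if (inherits(rule, "boolean_rule")) rule$expr else rule
  ev <- function(e, state) {
    switch(e$op,
      var = {
        v <- state[[e$name]]
        if (is.null(v)) stop(sprintf("missing value for node '%s'", e$name),
                             call. = FALSE)
        v
      },
      const = e$value,
      not   = 1 - ev(e$arg, state),
      and   = ev(e$lhs, state) * ev(e$rhs, state),
      or    = {
        a <- ev(e$lhs, state); b <- ev(e$rhs, state)
        a + b - a * b
      }
    )
  }
  function(state) ev(e, state)
}

# Compile an expression tree to an R expression over `x`, a numeric vector
# indexed by node position. Used by build_ode_system for fast repeated
# evaluation inside the ODE right-hand side.
#' @noRd
compile_fuzzy_expr <- function(e, index) {
  tx <- function(e) {
    switch(e$op,
      var = {
        i <- index[[e$name]]
        if (is.null(i) || is.na(i)) stop(sprintf("unknown node '%s'", e$name),
                                         call. = FALSE)
        sprintf("x[%dL]", i)
      },
      const = sprintf("%d", as.integer(e$value)),
      not   = sprintf("(1 - %s)", tx(e$arg)),
      and   = sprintf("(%s * %s)", tx(e$lhs), tx(e$rhs)),
      or    = {
        a <- tx(e$lhs); b <- tx(e$rhs)
        sprintf("(%s + %s - %s * %s)", a, b, a, b)
      }
    )
  }
  str2lang(tx(e))
}
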