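# BLTL abstract syntax: nested lists with a `kind` field.
#   atom  : var, rel ("<", ">", "="), value
#   not   : child
#   and/or: left, right
#   until : left, right, bound (>= 0)
# F[t] p is desugared to (p | !p) U[t] p and G[t] p to !F[t](!p); the
# originating sugar is kept for printing only.

bltl_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "bltl_formula")
}

tokenize_formula <- function(text) {
  pats <- c(
    ws = "^\\s+",
    number = "^[-+]?(\\d+\\.?\\d*|\\.\\d+)([eE][-+]?\\d+)?",
    ident = "^[A-Za-z_][A-Za-z0-9_.]*",
    punct = "^[][()!&|<>=]"
  )
  tokens <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    matched <- FALSE
    for (type in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[type]], rest))
      if (length(m) == 1L) {
        if (type != "ws") {
          tokens[[length(tokens) + 1L]] <-
            list(type = type, text = m, pos = pos)
        }
        pos <- pos + nchar(m)
        rest <- substr(rest, nchar(m) + 1L, nchar(rest))
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      abort(sprintf(
        "BLTL syntax error at position %d: unexpected character '%s'.",
        pos, substr(rest, 1, 1)
      ))
    }
  }
  tokens
}

#' Parse a BLTL formula
#'
#' Concrete syntax (in decreasing precedence): negation `!`, conjunction
#' `&`, disjunction `|`; atoms are `variable < value`, `variable > value`
#' or `variable = value`; temporal operators are `F[t](phi)` ("eventually
#' within time t"), `G[t](phi)` ("always within t") and the bounded Until
#' `(phi1) U[t] (phi2)`, which is non-associative and requires parentheses.
#' `F` and `G` are sugar: `F[t] p` is `(p | !p) U[t] p` and `G[t] p` is
#' `!F[t](!p)`.
#'
#' @param text Formula string, e.g. `"F[10](x > 1e11)"`.
#' @return An abstract syntax tree of class `bltl_formula`.
#' @examples
#' parse_formula("F[10](x > 3.3)")
#' parse_formula("x > 3 & !(y < 2)")
#' parse_formula("(x > 0) U[5] (y = 1)")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokenize_formula(text)
  st$i <- 1L

  peek <- function() if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
  advance <- function() {
    tok <- peek()
    st$i <- st$i + 1L
    tok
  }
  expect <- function(text_wanted) {
    tok <- advance()
    if (is.null(tok) || tok$text != text_wanted) {
      abort(sprintf(
        "BLTL syntax error at position %s: expected '%s'%s.",
        if (is.null(tok)) "end of input" else tok$pos, text_wanted,
        if (is.null(tok)) "" else sprintf(" but found '%s'", tok$text)
      ))
    }
    tok
  }
  expect_number <- function(what) {
    tok <- advance()
    if (is.null(tok) || tok$type != "number") {
      abort(sprintf(
        "BLTL syntax error at position %s: expected a number (%s).",
        if (is.null(tok)) "end of input" else tok$pos, what
      ))
    }
    as.numeric(tok$text)
  }

  parse_bound <- function() {
    expect("[")
    b <- expect_number("time bound")
    if (b < 0) abort("BLTL time bounds must be >= 0.")
    expect("]")
    b
  }
  make_F <- function(bound, phi) {
    u <- bltl_node(
      "until",
      left = bltl_node("or", left = phi, right = bltl_node("not", child = phi)),
      right = phi, bound = bound
    )
    u$sugar <- "F"
    u
  }
  make_G <- function(bound, phi) {
    g <- bltl_node(
      "not",
      child = make_F(bound, bltl_node("not", child = phi))
    )
    g$sugar <- "G"
    g$sugar_bound <- bound
    g$sugar_child <- phi
    g
  }

  parse_unary <- function() {
    tok <- peek()
    if (is.null(tok)) abort("BLTL syntax error: unexpected end of input.")
    if (tok$text == "!") {
      advance()
      return(bltl_node("not", child = parse_unary()))
    }
    if (tok$type == "ident" && tok$text %in% c("F", "G") &&
        st$i < length(st$tokens) && st$tokens[[st$i + 1L]]$text == "[") {
      op <- advance()$text
      bound <- parse_bound()
      expect("(")
      phi <- parse_or()
      expect(")")
      return(if (op == "F") make_F(bound, phi) else make_G(bound, phi))
    }
    if (tok$text == "(") {
      advance()
      phi <- parse_or()
      expect(")")
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "ident" && nxt$text == "U" &&
          st$i < length(st$tokens) && st$tokens[[st$i + 1L]]$text == "[") {
        advance()
        bound <- parse_bound()
        expect("(")
        phi2 <- parse_or()
        expect(")")
        return(bltl_node("until", left = phi, right = phi2, bound = bound))
      }
      return(phi)
    }
    if (tok$type == "ident") {
      advance()
      rel <- advance()
      if (is.null(rel) || !rel$text %in% c("<", ">", "=")) {
        abort(sprintf(
          "BLTL syntax error at position %s: expected one of '<', '>', '=' after variable '%s'.",
          if (is.null(rel)) "end of input" else rel$pos, tok$text
        ))
      }
      value <- expect_number("comparison threshold")
      return(bltl_node("atom", var = tok$text, rel = rel$text, value = value))
    }
    abort(sprintf(
      "BLTL syntax error at position %d: unexpected token '%s'.",
      tok$pos, tok$text
    ))
  }
  parse_and <- function() {
    node <- parse_unary()
    while (!is.null(peek()) && peek()$text == "&") {
      advance()
      node <- bltl_node("and", left = node, right = parse_unary())
    }
    node
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.null(peek()) && peek()$text == "|") {
      advance()
      node <- bltl_node("or", left = node, right = parse_and())
    }
    node
  }

  out <- parse_or()
  tok <- peek()
  if (!is.null(tok)) {
    abort(sprintf(
      "BLTL syntax error at position %d: unexpected trailing '%s'.",
      tok$pos, tok$text
    ))
  }
  out
}

#' @export
format.bltl_formula <- function(x, ...) {
  fmt <- function(node) {
    if (!is.null(node$sugar)) {
      if (node$sugar == "F") {
        return(sprintf("F[%g](%s)", node$bound, fmt(node$right)))
      }
      return(sprintf("G[%g](%s)", node$sugar_bound, fmt(node$sugar_child)))
    }
    switch(node$kind,
      atom = sprintf("%s %s %g", node$var, node$rel, node$value),
      not = sprintf("!(%s)", fmt(node$child)),
      and = sprintf("(%s) & (%s)", fmt(node$left), fmt(node$right)),
      or = sprintf("(%s) | (%s)", fmt(node$left), fmt(node$right)),
      until = sprintf("(%s) U[%g] (%s)", fmt(node$left), node$bound,
                      fmt(node$right))
    )
  }
  fmt(x)
}

#' @export
print.bltl_formula <- function(x, ...) {
  cat("<bltl_formula>", format(x), "\n")
  invisible(x)
}

#' Variables referenced by a formula
#'
#' @param formula A `bltl_formula`.
#' @return Character vector of the distinct atom variables.
#' @examples
#' formula_variables(parse_formula("x > 3 & !(y < 2)"))
#' @export
formula_variables <- function(formula) {
  vars <- character()
  walk <- function(node) {
    switch(node$kind,
      atom = vars[[length(vars) + 1L]] <<- node$var,
      not = walk(node$child),
      and = ,
      or = {
        walk(node$left)
        walk(node$right)
      },
      until = {
        walk(node$left)
        walk(node$right)
      }
    )
    invisible(NULL)
  }
  walk(formula)
  unique(vars)
}

# Largest time bound appearing in the formula (for horizon warnings).
formula_horizon <- function(formula) {
  h <- 0
  walk <- function(node) {
    if (node$kind == "until") h <<- max(h, node$bound)
    for (f in c("child", "left", "right")) {
      if (!is.null(node[[f]])) walk(node[[f]])
    }
  }
  walk(formula)
  h
}
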