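## Boolean expression trees for GPR rules and network update functions.
##
## A bool_expr is a plain list with an `op` field:
##   op = "const": val (0 or 1)
##   op = "lit":   var (gene / node id, opaque nonempty string)
##   op = "not":   arg (bool_expr)
##   op = "and" / "or": args (list of >= 2 bool_expr)

new_expr <- function(x) structure(x, class = "bool_expr")

#' Boolean expression constructors
#'
#' Build expression trees over gene/node identifiers.  `bx_and()` and
#' `bx_or()` are n-ary and collapse to their single argument when given one.
#'
#' @param val 0 or 1.
#' @param var Nonempty identifier string.
#' @param x A `bool_expr`.
#' @param ... `bool_expr` operands.
#' @return A `bool_expr`.
#' @export
bx_const <- function(val) {
  stopifnot(val %in% c(0L, 1L))
  new_expr(list(op = "const", val = as.integer(val)))
}

#' @rdname bx_const
#' @export
bx_lit <- function(var) {
  if (!is.character(var) || length(var) != 1L || !nzchar(var)) {
    stop2("gene/node identifier must be a nonempty string")
  }
  new_expr(list(op = "lit", var = var))
}

#' @rdname bx_const
#' @export
bx_not <- function(x) new_expr(list(op = "not", arg = x))

#' @rdname bx_const
#' @export
bx_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "bool_expr")) {
    args <- args[[1L]]
  }
  if (length(args) == 0L) stop2("bx_and() needs at least one operand")
  if (length(args) == 1L) return(args[[1L]])
  new_expr(list(op = "and", args = args))
}

#' @rdname bx_const
#' @export
bx_or <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "bool_expr")) {
    args <- args[[1L]]
  }
  if (length(args) == 0L) stop2("bx_or() needs at least one operand")
  if (length(args) == 1L) return(args[[1L]])
  new_expr(list(op = "or", args = args))
}

is_const_expr <- function(x, val = NULL) {
  x$op == "const" && (is.null(val) || x$val == val)
}

#' Variables of a Boolean expression
#'
#' @param x A `bool_expr`.
#' @return Sorted character vector of the distinct literal identifiers.
#' @export
expr_vars <- function(x) {
  acc <- character()
  walk <- function(e) {
    switch(e$op,
      const = NULL,
      lit = acc[[length(acc) + 1L]] <<- e$var,
      not = walk(e$arg),
      and = ,
      or = for (a in e$args) walk(a)
    )
    invisible(NULL)
  }
  walk(x)
  csort(unique(acc))
}

#' Evaluate a Boolean expression
#'
#' @param x A `bool_expr`.
#' @param env Named integer/logical vector giving values (0/1) for every
#'   variable of `x`.
#' @return 0L or 1L.
#' @export
eval_expr <- function(x, env) {
  switch(x$op,
    const = x$val,
    lit = {
      v <- env[[x$var]]
      if (is.null(v) || is.na(v)) stop2("no value for variable '", x$var, "'")
      as.integer(v)
    },
    not = 1L - eval_expr(x$arg, env),
    and = {
      for (a in x$args) if (eval_expr(a, env) == 0L) return(0L)
      1L
    },
    or = {
      for (a in x$args) if (eval_expr(a, env) == 1L) return(1L)
      0L
    }
  )
}

## Truth table over the expression's own (sorted) variables.
## Row index = 1 + sum(bit_i * 2^(i-1)) over vars in order.
expr_tt <- function(x, vars = expr_vars(x)) {
  k <- length(vars)
  if (k > 16L) stop2("expression over ", k, " variables: truth table too large")
  nrows <- bitwShiftL(1L, k)
  tt <- integer(nrows)
  env <- integer(k)
  names(env) <- vars
  for (i in seq_len(nrows) - 1L) {
    for (j in seq_len(k)) env[[j]] <- bitwAnd(bitwShiftR(i, j - 1L), 1L)
    tt[i + 1L] <- eval_expr(x, env)
  }
  list(vars = vars, tt = tt)
}

## ---- GPR grammar ------------------------------------------------------

## Tokens: identifiers, keywords and/or/not (case-insensitive), &, |, !,
## parentheses; "0"/"1" parse as constants.
gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      push("lparen", "(", i); i <- i + 1L
    } else if (ch == ")") {
      push("rparen", ")", i); i <- i + 1L
    } else if (ch == "&") {
      push("and", "&", i); i <- i + 1L
    } else if (ch == "|") {
      push("or", "|", i); i <- i + 1L
    } else if (ch == "!") {
      push("not", "!", i); i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[\\s()&|!]$", chars[[j]], perl = TRUE)) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      if (lw == "and") push("and", word, i)
      else if (lw == "or") push("or", word, i)
      else if (lw == "not") push("not", word, i)
      else if (word %in% c("0", "1")) push("const", word, i)
      else push("ident", word, i)
      i <- j
    }
  }
  toks
}

#' Parse a gene-protein-reaction (GPR) rule
#'
#' Accepts the usual GPR grammar: identifiers combined with `and`/`or`/`not`
#' (case-insensitive) or the symbolic spellings `&`/`|`/`!`, with parentheses;
#' precedence is NOT > AND > OR.  `0` and `1` parse as constants.
#'
#' @param text GPR string.
#' @return A `bool_expr`.
#' @export
#' @examples
#' parse_gpr("(g1 or g2) and g3")
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L) stop2("GPR must be a single string")
  toks <- gpr_tokenize(text)
  if (length(toks) == 0L) stop2("empty GPR expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_more <- function(what) {
    t <- peek()
    if (is.null(t)) stop2("GPR parse error: expected ", what, " at end of '", text, "'")
    t
  }
  parse_or <- function() {
    left <- parse_and()
    parts <- list(left)
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1L]] else new_expr(list(op = "or", args = parts))
  }
  parse_and <- function() {
    parts <- list(parse_not())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parse_not()
    }
    if (length(parts) == 1L) parts[[1L]] else new_expr(list(op = "and", args = parts))
  }
  parse_not <- function() {
    t <- expect_more("an operand")
    if (t$type == "not") {
      advance()
      bx_not(parse_not())
    } else {
      parse_primary()
    }
  }
  parse_primary <- function() {
    t <- expect_more("an operand")
    if (t$type == "lparen") {
      advance()
      inner <- parse_or()
      cl <- peek()
      if (is.null(cl) || cl$type != "rparen") {
        stop2("GPR parse error: unbalanced parentheses in '", text, "'")
      }
      advance()
      inner
    } else if (t$type == "ident") {
      advance()
      bx_lit(t$value)
    } else if (t$type == "const") {
      advance()
      bx_const(as.integer(t$value))
    } else {
      stop2("GPR parse error: unexpected '", t$value, "' at position ", t$pos,
            " in '", text, "'")
    }
  }
  out <- parse_or()
  if (pos <= length(toks)) {
    t <- toks[[pos]]
    stop2("GPR parse error: unexpected '", t$value, "' at position ", t$pos,
          " in '", text, "'")
  }
  out
}

#' Render a Boolean expression as a GPR string
#'
#' Produces lowercase `and`/`or`/`not` keywords with minimal parentheses;
#' `parse_gpr(render_gpr(x))` reproduces the tree.
#'
#' @param x A `bool_expr`.
#' @return A string.
#' @export
render_gpr <- function(x) {
  prec <- c(or = 1L, and = 2L, not = 3L, lit = 4L, const = 4L)
  rend <- function(e, parent_prec) {
    p <- prec[[e$op]]
    s <- switch(e$op,
      const = as.character(e$val),
      lit = e$var,
      not = paste0("not ", rend(e$arg, p)),
      and = paste(vapply(e$args, rend, "", parent_prec = p + 1L), collapse = " and "),
      or = paste(vapply(e$args, rend, "", parent_prec = p + 1L), collapse = " or ")
    )
    if (p < parent_prec) paste0("(", s, ")") else s
  }
  rend(x, 0L)
}

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", render_gpr(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bool_expr <- function(x, ...) render_gpr(x)
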