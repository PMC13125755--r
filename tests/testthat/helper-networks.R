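# shared generators for property-style tests (all seeded by the caller)

# random expression tree over `vars`; with_not = FALSE gives monotone trees
random_expr <- function(vars, depth = 3L, with_not = TRUE) {
  if (depth == 0L || stats::runif(1) < 0.35) {
    return(bx_lit(sample(vars, 1L)))
  }
  op <- sample(if (with_not) c("and", "or", "not") else c("and", "or"), 1L)
  if (op == "not") {
    bx_not(random_expr(vars, depth - 1L, with_not))
  } else {
    k <- sample(2:3, 1L)
    args <- lapply(seq_len(k), function(i) random_expr(vars, depth - 1L, with_not))
    if (op == "and") bx_and(args) else bx_or(args)
  }
}

# pure-GPR network: a marker node driven by `expr`, all genes free inputs
pure_gpr_network <- function(expr, marker = "Rx") {
  genes <- expr_vars(expr)
  f <- c(stats::setNames(list(expr), marker),
         stats::setNames(lapply(genes, bx_lit), genes))
  boolean_network(f)
}

iv_labels <- function(ivs) {
  vapply(ivs, function(x) {
    iv <- if (inherits(x, "gmis")) x$interventions else x
    paste0("KO{", paste(iv$KO, collapse = ","), "}KI{", paste(iv$KI, collapse = ","), "}")
  }, "")
}
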