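mk_expr <- function(vals, samples = "s1") {
  m <- matrix(unlist(vals), nrow = length(vals), ncol = length(samples),
              dimnames = list(names(vals), samples))
  structure(m, class = c("expression_matrix", class(m)))
}

test_that("essentiality calls require a unique highly expressed knockout member", {
  g12 <- intervention_set(KO = c("g1", "g2"))
  # g1 silent, g2 high: the pair collapses to the single knockdown of g2
  pred <- predict_essential(list(g12), mk_expr(c(g1 = 0, g2 = 5)))
  expect_equal(pred$s1$gene, "g2")
  # both high: no unique member, no call
  pred <- predict_essential(list(g12), mk_expr(c(g1 = 5, g2 = 5)))
  expect_equal(nrow(pred$s1), 0L)
  # mixed intervention: knock-in context must be highly expressed
  g34 <- intervention_set(KO = "g3", KI = "g4")
  pred <- predict_essential(list(g34), mk_expr(c(g3 = 5, g4 = 5)))
  expect_equal(pred$s1$gene, "g3")
  pred <- predict_essential(list(g34), mk_expr(c(g3 = 5, g4 = 0)))
  expect_equal(nrow(pred$s1), 0L)
  # missing genes are reported
  expect_error(predict_essential(list(g34), mk_expr(c(g3 = 5))), "g4")
})

test_that("threshold changes act through the gene itself or its context only", {
  set.seed(19)
  ivs <- list(intervention_set(KO = c("gA", "gB")),
              intervention_set(KO = c("gB", "gC"), KI = "gD"))
  genes <- c("gA", "gB", "gC", "gD")
  for (rep in 1:20) {
    expr <- mk_expr(stats::setNames(as.list(runif(4, 0, 3)), genes))
    t1 <- runif(1, 0, 1.5); t2 <- t1 + runif(1, 0.1, 1.5)
    p1 <- predict_essential(ivs, expr, screening_config(expr_high_threshold = t1))$s1$gene
    p2 <- predict_essential(ivs, expr, screening_config(expr_high_threshold = t2))$s1$gene
    for (g in setdiff(p2, p1)) {
      # a call appearing at the higher threshold can only come from a context
      # knockout partner dropping out of the "high" set, never from g itself
      expect_gt(expr[g, 1], t2)
      partners <- unlist(lapply(ivs, function(iv) if (g %in% iv$KO) setdiff(iv$KO, g) else NULL))
      expect_true(any(expr[partners, 1] > t1 & expr[partners, 1] <= t2))
    }
    for (g in setdiff(p1, p2)) {
      # a call lost at the higher threshold lost either g or a knock-in partner
      involved <- unlist(lapply(ivs, function(iv) if (g %in% iv$KO) c(g, iv$KI) else NULL))
      expect_true(any(expr[involved, 1] > t1 & expr[involved, 1] <= t2))
    }
  }
})

test_that("adaptation check flags regulatory escape around partner knockouts", {
  # antagonistic wiring: knocking out g1 forces g2 on in the only attractor
  bn <- boolean_network(list(g1 = bx_lit("g1"), g2 = bx_not(bx_lit("g1"))))
  expect_false(adaptation_check(bn, intervention_set(KO = c("g1", "g2"))))
  # co-activation: knocking out g1 keeps g2 off
  bn <- boolean_network(list(g1 = bx_lit("g1"), g2 = bx_lit("g1")))
  expect_true(adaptation_check(bn, intervention_set(KO = c("g1", "g2"))))
  # singletons pass vacuously
  expect_true(adaptation_check(bn, intervention_set(KO = "g1")))
})

test_that("adaptation check always passes for unlinked gMIS members", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    nodes <- paste0("x", seq_len(n))
    f <- stats::setNames(lapply(nodes, bx_lit), nodes)   # independent inputs
    bn <- boolean_network(f)
    members <- sample(nodes, sample(2:n, 1))
    expect_true(adaptation_check(bn, intervention_set(KO = members)))
  }
})

test_that("screen labelling applies the published cutoffs exactly", {
  sc <- structure(matrix(c(-0.61, -0.6, -0.59), 3, 1,
                         dimnames = list(c("a", "b", "c"), "s1")),
                  platform = "depmap", class = "dependency_scores")
  expect_equal(unname(label_dependencies(sc)[, 1]), c(1L, 1L, 0L))
  ps <- structure(matrix(c(-0.1, 0, 0.01), 3, 1,
                         dimnames = list(c("a", "b", "c"), "s1")),
                  platform = "project_score", class = "dependency_scores")
  expect_equal(unname(label_dependencies(ps)[, 1]), c(0L, 0L, 1L))
  # missing stays missing
  sc[2, 1] <- NA
  expect_equal(unname(label_dependencies(sc)[, 1]), c(1L, NA, 0L))
})

test_that("MCC handles perfect, inverted, balanced and degenerate counts", {
  expect_equal(compute_mcc(list(TP = 10, TN = 10, FP = 0, FN = 0)), 1)
  expect_equal(compute_mcc(list(TP = 0, TN = 0, FP = 10, FN = 10)), -1)
  expect_equal(compute_mcc(list(TP = 1, TN = 1, FP = 1, FN = 1)), 0)
  expect_equal(compute_mcc(list(TP = 0, TN = 5, FP = 0, FN = 0)), 0)
  expect_error(compute_mcc(list(TP = -1, TN = 0, FP = 0, FN = 0)), "non-negative")
})

test_that("evaluation pools per-sample confusion counts additively", {
  labels <- matrix(c(1L, 0L, 0L, 1L, 0L, 0L), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  pred <- list(s1 = "a", s2 = c("a", "b"))
  res <- evaluate_predictions(pred, labels, universe = c("a", "b", "c"))
  expect_equal(res$TP, c(1L, 1L))
  expect_equal(res$FP, c(0L, 1L))
  expect_equal(res$MCC[1], 1)
  pooled <- attr(res, "pooled_mcc")
  expect_equal(pooled, compute_mcc(list(TP = 2, FP = 1, TN = 3, FN = 0)))
  expect_error(evaluate_predictions(pred, labels, universe = character(0)), "empty")
  # all-negative sample scores 0 by the zero-factor convention
  res0 <- evaluate_predictions(list(s1 = character(0)),
                               matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s1")),
                               universe = c("a", "b"))
  expect_equal(res0$MCC, 0)
  expect_equal(res0$TN, 2L)
})
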