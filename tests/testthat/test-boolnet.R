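toggle4 <- function() {
  boolean_network(list(Rx = bx_lit("g1"), g1 = bx_lit("r1"),
                       r1 = bx_not(bx_lit("r2")), r2 = bx_not(bx_lit("r1"))))
}

test_that("minimal trap spaces match hand-derived attractors", {
  # constant node: single fixed point
  ts <- minimal_trap_spaces(boolean_network(list(a = bx_const(1L))))
  expect_equal(ts, list(c(a = 1L)))

  # mutual-repression toggle: two fixed points
  bn <- boolean_network(list(r1 = bx_not(bx_lit("r2")), r2 = bx_not(bx_lit("r1"))))
  expect_equal(minimal_trap_spaces(bn),
               list(c(r1 = 0L, r2 = 1L), c(r1 = 1L, r2 = 0L)))

  # 4-node cascade on top of the toggle (nodes in canonical C-collation order)
  expect_equal(minimal_trap_spaces(toggle4()),
               list(c(Rx = 0L, g1 = 0L, r1 = 0L, r2 = 1L),
                    c(Rx = 1L, g1 = 1L, r1 = 1L, r2 = 0L)))

  # negative self-loop: everything oscillates, one all-free trap space
  bn <- boolean_network(list(g1 = bx_not(bx_lit("g1"))))
  expect_equal(minimal_trap_spaces(bn), list(c(g1 = NA_integer_)))
})

test_that("trap spaces equal the exhaustive subcube oracle on a seeded corpus", {
  for (s in 1:25) {
    n <- 3L + (s %% 6L)
    bn <- random_boolean_network(n, 2L, seed = 400L + s)
    expect_identical(minimal_trap_spaces(bn), trap_spaces_exhaustive(bn),
                     label = sprintf("network seed %d (n=%d)", 400L + s, n))
  }
})

test_that("perturbations replace functions by constants and validate genes", {
  bn <- toggle4()
  expect_identical(apply_perturbation(bn, intervention_set()), bn)

  p <- apply_perturbation(bn, intervention_set(KO = "g1"))
  expect_equal(p$f[["g1"]], bx_const(0L))
  expect_equal(p$f[["r1"]], bn$f[["r1"]])
  ts <- minimal_trap_spaces(p)
  expect_true(all(vapply(ts, function(s) s[["Rx"]] == 0L, logical(1))))

  expect_error(intervention_set(KO = "g1", KI = "g1"), "both")
  expect_error(apply_perturbation(bn, intervention_set(KO = "zz")), "zz")
})

test_that("minimal inactivating sets solve AND/OR GPRs and the cyclic toggle", {
  # AND: either conjunct suffices
  bn <- pure_gpr_network(parse_gpr("g1 and g2"))
  expect_equal(iv_labels(minimal_inactivating_sets(bn, "Rx", kmax = 2L)),
               c("KO{g1}KI{}", "KO{g2}KI{}"))
  # OR: both disjuncts needed
  bn <- pure_gpr_network(parse_gpr("g1 or g2"))
  expect_equal(iv_labels(minimal_inactivating_sets(bn, "Rx", kmax = 2L)),
               "KO{g1,g2}KI{}")
  # cyclic toggle: knockout of the cascade or knock-in of the repressor
  expect_equal(iv_labels(minimal_inactivating_sets(toggle4(), "Rx", kmax = 1L)),
               c("KO{g1}KI{}", "KO{r1}KI{}", "KO{}KI{r2}"))
})

test_that("inactivating sets equal the exhaustive signed-subset oracle", {
  for (s in 1:8) {
    n <- 3L + (s %% 4L)
    bn <- random_boolean_network(n, 2L, seed = 500L + s)
    marker <- bn$nodes[[1L]]
    expect_identical(minimal_inactivating_sets(bn, marker, kmax = 2L),
                     inactivating_sets_exhaustive(bn, marker, kmax = 2L),
                     label = sprintf("network seed %d", 500L + s))
  }
})

test_that("returned intervention sets form an antichain", {
  for (s in c(3L, 9L, 14L)) {
    bn <- random_boolean_network(6L, 2L, seed = 600L + s)
    ivs <- minimal_inactivating_sets(bn, bn$nodes[[1L]], kmax = 3L)
    for (i in seq_along(ivs)) {
      for (j in seq_along(ivs)) {
        if (i != j) expect_false(gmisnet:::iv_subset(ivs[[i]], ivs[[j]]))
      }
    }
  }
})

test_that("an unread extra input node changes no inactivating set", {
  bn <- toggle4()
  f2 <- bn$f
  f2$spare <- bx_lit("spare")
  bn2 <- boolean_network(f2)
  expect_identical(iv_labels(minimal_inactivating_sets(bn, "Rx", kmax = 2L,
                                                       candidates = setdiff(bn$nodes, "Rx"))),
                   iv_labels(minimal_inactivating_sets(bn2, "Rx", kmax = 2L,
                                                       candidates = setdiff(bn$nodes, "Rx"))))
})

test_that("acyclic KO-only results equal minimal transversals of prime implicants", {
  set.seed(77)
  for (i in 1:20) {
    expr <- random_expr(c("gA", "gB", "gC", "gD"), depth = 2L, with_not = FALSE)
    bn <- pure_gpr_network(expr)
    ivs <- minimal_inactivating_sets(bn, "Rx", kmax = 3L)
    ko_only <- Filter(function(iv) length(iv$KI) == 0L, ivs)
    # independent route: hitting sets of the prime implicants' positive literals
    pis <- gmisnet:::prime_implicants(expr, 1L)
    pos <- lapply(pis, function(p) names(p)[p == 1L])
    genes <- expr_vars(expr)
    hits <- list()
    for (size in 1:3) {
      if (size > length(genes)) break
      for (sel in utils::combn(genes, size, simplify = FALSE)) {
        if (any(vapply(hits, function(h) all(h %in% sel), logical(1)))) next
        if (all(vapply(pos, function(pp) any(pp %in% sel), logical(1)))) {
          hits[[length(hits) + 1L]] <- sel
        }
      }
    }
    expect_setequal(vapply(ko_only, function(iv) paste(iv$KO, collapse = ","), ""),
                    vapply(hits, paste, "", collapse = ","))
  }
})
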