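test_that("blocked_reactions fires rows by signed containment", {
  b <- make_toy_gem("plain")
  gd <- build_gdict(b$model, b$regnet, layers = 0L)
  expect_equal(blocked_reactions(gd, intervention_set(KO = "g1")), "R1")
  expect_equal(blocked_reactions(gd, intervention_set(KO = c("g1", "g3"))), c("R1", "R2"))
  expect_equal(blocked_reactions(gd, intervention_set()), character(0))
})

test_that("blocks_target reproduces hand-solved flux outcomes", {
  b <- make_toy_gem("plain")
  gd <- build_gdict(b$model, b$regnet, layers = 0L)
  cfg <- solver_config()
  expect_false(blocks_target(b$model, gd, intervention_set(), cfg))
  expect_false(blocks_target(b$model, gd, intervention_set(KO = "g1"), cfg))
  expect_true(blocks_target(b$model, gd, intervention_set(KO = c("g1", "g3")), cfg))
})

test_that("gMIS enumeration matches ground truth and brute force on all variants", {
  expected_n <- c(plain = 2L, activator = 4L, repressor = 6L)
  for (v in names(expected_n)) {
    b <- make_toy_gem(v)
    gd <- build_gdict(b$model, b$regnet, layers = b$ground_truth$layers)
    cfg <- solver_config(max_size = 2L)
    gm <- enumerate_gmis(b$model, gd, cfg)
    expect_length(gm, expected_n[[v]])
    expect_identical(lapply(gm, `[[`, "interventions"), b$ground_truth$gmis,
                     label = v)
    expect_identical(gm, gmis_exhaustive(b$model, gd, cfg), label = v)
  }
})

test_that("every gMIS is sound and minimal under single removals", {
  b <- make_toy_gem("repressor")
  gd <- build_gdict(b$model, b$regnet, layers = 1L)
  cfg <- solver_config(max_size = 2L)
  gm <- enumerate_gmis(b$model, gd, cfg)
  for (g in gm) {
    iv <- g$interventions
    expect_length(intersect(iv$KO, iv$KI), 0L)
    expect_true(blocks_target(b$model, gd, iv, cfg))
    for (ko in iv$KO) {
      expect_false(blocks_target(b$model, gd,
                                 intervention_set(KO = setdiff(iv$KO, ko), KI = iv$KI), cfg))
    }
    for (ki in iv$KI) {
      expect_false(blocks_target(b$model, gd,
                                 intervention_set(KO = iv$KO, KI = setdiff(iv$KI, ki)), cfg))
    }
  }
  # antichain across the solution list
  for (i in seq_along(gm)) {
    for (j in seq_along(gm)) {
      if (i != j) expect_false(gmisnet:::iv_subset(gm[[i]]$interventions, gm[[j]]$interventions))
    }
  }
})

test_that("zero regulatory layers reproduce classical gene-level cut sets", {
  for (v in c("plain", "activator", "repressor")) {
    b <- make_toy_gem(v)
    gd <- build_gdict(b$model, b$regnet, layers = 0L)
    gm <- enumerate_gmis(b$model, gd, solver_config(max_size = 2L))
    expect_true(all(vapply(gm, function(g) length(g$interventions$KI) == 0L, logical(1))))
    got <- lapply(gm, function(g) g$interventions$KO)
    # independent route: prime implicants of the flux-feasibility function
    expect_identical(got, gene_mcs_from_gpr(b$model, max_size = 2L), label = v)
  }
})

test_that("unblockable targets yield an empty list and max_solutions caps output", {
  # target with no genetic route at all
  m <- metabolic_model(c("up", "out"), "A", matrix(c(1, -1), 1, 2),
                       lb = c(0, 0), ub = c(10, 10), target = "out")
  gd <- build_gdict(m, regulatory_network(), layers = 0L)
  expect_length(enumerate_gmis(m, gd, solver_config(max_size = 3L)), 0L)

  b <- make_toy_gem("repressor")
  gdb <- build_gdict(b$model, b$regnet, layers = 1L)
  gm1 <- enumerate_gmis(b$model, gdb, solver_config(max_size = 2L, max_solutions = 3L))
  expect_length(gm1, 3L)
})

test_that("gMIS TSV output carries ranks, signed genes and blocked reactions", {
  b <- make_toy_gem("repressor")
  gd <- build_gdict(b$model, b$regnet, layers = 1L)
  gm <- enumerate_gmis(b$model, gd, solver_config(max_size = 2L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gmis_tsv(gm, p)
  df <- utils::read.delim(p, colClasses = "character")
  expect_equal(nrow(df), 6L)
  expect_equal(df$KO[df$KI == "r4"], c("g1", "g2"))
  expect_true(all(df$blocked_reactions == "R1;R2"))
})
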