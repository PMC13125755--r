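test_that("JSON model dialect round-trips byte-identically", {
  for (variant in c("plain", "repressor")) {
    m <- make_toy_gem(variant)$model
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, p1)
    m2 <- load_metabolic_model(p1, "json")
    write_model_json(m2, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_identical(unclass(m2), unclass(m))
  }
})

test_that("toy fixture loads back with expected structure", {
  b <- make_toy_gem("plain")
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(b$model, p)
  m <- load_metabolic_model(p, "json")
  expect_equal(length(m$reactions), 4L)
  expect_equal(model_genes(m), c("g1", "g2", "g3"))
  expect_equal(m$target, "R_bm")
  expect_equal(dim(m$S), c(2L, 4L))
  # reactions without a GPR are unconstrained
  expect_null(m$gpr[["R_up"]])
})

test_that("SBML subset round-trips the model", {
  m <- make_toy_gem("activator")$model
  p <- withr::local_tempfile(fileext = ".sbml")
  write_model_sbml(m, p)
  m2 <- load_metabolic_model(p, "sbml")
  expect_identical(unclass(m2), unclass(m))
  # fbc cannot express NOT
  bad <- metabolic_model("R1", character(0), matrix(0, 0, 1), 0, 1,
                         list(R1 = "not g1"), "R1")
  expect_error(write_model_sbml(bad, withr::local_tempfile()), "NOT|not")
})

test_that("model validation catches inverted bounds and bad targets", {
  expect_error(metabolic_model("R1", "A", matrix(1, 1, 1), lb = 5, ub = 1,
                               target = "R1"), "lb > ub")
  expect_error(metabolic_model("R1", "A", matrix(1, 1, 1), lb = 0, ub = 1,
                               target = "Rz"), "target")
})

test_that("regulatory network TSV loading normalizes, dedupes and flags conflicts", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tsign",
               "r1\tg1\t+",
               "r1\tg1\t+",
               "r2\tg1\tactivation",
               "r3\tg2\trepression"), p)
  rn <- load_regulatory_network(p)
  expect_equal(nrow(rn), 3L)
  expect_equal(rn$sign[rn$source == "r3"], -1L)

  writeLines(c("r1\tg1\t+1", "r1\tg1\t-1"), p)
  expect_warning(rn2 <- load_regulatory_network(p), "conflicting")
  expect_equal(nrow(rn2), 2L)

  writeLines(c("r1\tg1\tmaybe"), p)
  expect_error(load_regulatory_network(p), "row 1")
})

test_that("matrix CSV loading validates genes and numeric cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,0.5,2", "g2,1,3"), p)
  m <- load_matrix(p, "expression")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["g2", "s2"]), 3)

  writeLines(c("gene,s1", "g1,1", "g1,2"), p)
  expect_error(load_matrix(p, "expression"), "duplicated")

  writeLines(c("gene,s1", "g1,abc"), p)
  expect_error(load_matrix(p, "expression"), "non-numeric.*g1")

  writeLines("gene", p)
  expect_error(load_matrix(p, "expression"), "sample")

  writeLines(c("gene,s1", "g1,-0.7"), p)
  expect_error(load_matrix(p, "scores"), "platform")
  sc <- load_matrix(p, "scores", platform = "depmap")
  expect_equal(attr(sc, "platform"), "depmap")
})

test_that("GDict JSON round-trips and rejects K/N overlap", {
  b <- make_toy_gem("repressor")
  gd <- build_gdict(b$model, b$regnet, layers = 1L)
  p <- withr::local_tempfile(fileext = ".json")
  write_gdict(gd, p)
  gd2 <- read_gdict(p, reaction_order = b$model$reactions)
  expect_identical(gd2$rows, gd$rows)
  expect_equal(gd2$provenance$layers, 1L)

  # empty GDict round-trips too
  empty <- gmisnet:::new_gdict(list())
  write_gdict(empty, p)
  expect_length(read_gdict(p)$rows, 0L)

  # hand-edited overlap is rejected
  writeLines('{"R1": [{"K": ["g1"], "N": ["g1"]}]}', p)
  expect_error(read_gdict(p), "both K and N")
})

test_that(".bnet export uses the node, function line format", {
  bn <- boolean_network(list(a = bx_not(bx_lit("b")), b = bx_lit("b")))
  p <- withr::local_tempfile(fileext = ".bnet")
  write_bnet(bn, p)
  expect_equal(readLines(p), c("targets, factors", "a, !b", "b, b"))
})
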