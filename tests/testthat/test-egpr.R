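test_that("regulator combination follows the activator/repressor rule", {
  expect_equal(render_gpr(combine_regulators("r1", character(0))), "r1")
  expect_equal(render_gpr(combine_regulators(c("r2", "r1"), "r3")),
               "(r1 or r2) and not r3")
  expect_equal(render_gpr(combine_regulators(character(0), "r4")), "not r4")
  expect_error(combine_regulators(character(0), character(0)), "at least one")
})

test_that("layers = 0 reproduces the bare GPR with free gene inputs", {
  tg <- make_toggle_fixture()
  eg <- expand_reaction(tg$model, tg$regnet, "R1", layers = 0L)
  expect_equal(eg$nodes, c("R1", "g1"))
  expect_equal(eg$f[["R1"]], bx_lit("g1"))
  expect_true(gmisnet:::bn_is_input(eg, "g1"))
  expect_equal(unname(eg$layer), c(0L, 0L))
})

test_that("toggle fixture expands to the expected cyclic network", {
  tg <- make_toggle_fixture()
  eg <- expand_reaction(tg$model, tg$regnet, "R1", layers = 2L)
  expect_equal(eg$nodes, c("R1", "g1", "r1", "r2"))
  expect_equal(render_gpr(eg$f[["R1"]]), "g1")
  expect_equal(render_gpr(eg$f[["g1"]]), "r1")
  expect_equal(render_gpr(eg$f[["r1"]]), "not r2")
  expect_equal(render_gpr(eg$f[["r2"]]), "not r1")
  expect_equal(eg$layer[c("g1", "r1", "r2")], c(g1 = 0L, r1 = 1L, r2 = 2L))
  expect_true(check_target_reachable(eg, "R1"))
})

test_that("reachability distinguishes fixed, free, and blocked markers", {
  # marker constant 0: never reachable
  bn <- boolean_network(list(Rx = bx_const(0L)))
  expect_false(check_target_reachable(bn, "Rx"))
  # marker that is a free input: reachable (fixed to 1 in one attractor)
  bn <- boolean_network(list(Rx = bx_lit("Rx")))
  expect_true(check_target_reachable(bn, "Rx"))
  # oscillating marker: reachable permissively, not strictly
  bn <- boolean_network(list(Rx = bx_lit("g1"), g1 = bx_not(bx_lit("g1"))))
  expect_true(check_target_reachable(bn, "Rx", sense = "permissive"))
  expect_false(check_target_reachable(bn, "Rx", sense = "strict"))
})

test_that("negative self-regulation is reverted under the strict sense only", {
  m <- metabolic_model("Rx", character(0), matrix(0, 0, 1), 0, 10,
                       list(Rx = "g1"), "Rx")
  rn <- regulatory_network("g1", "g1", -1L)
  # permissive: the all-free trap space keeps the marker attainable
  egp <- expand_reaction(m, rn, "Rx", layers = 1L, sense = "permissive")
  expect_equal(render_gpr(egp$f[["g1"]]), "not g1")
  expect_equal(egp$log$action, "kept")
  # strict: no attractor fixes the marker to 1, so the expansion is reverted
  egs <- expand_reaction(m, rn, "Rx", layers = 1L, sense = "strict")
  expect_true(gmisnet:::bn_is_input(egs, "g1"))
  expect_equal(egs$log$action, "reverted")
})

test_that("expansion is deterministic and keeps regulators outside the horizon free", {
  m <- metabolic_model("Rz", character(0), matrix(0, 0, 1), 0, 10,
                       list(Rz = "gA and gB"), "Rz")
  rn <- regulatory_network(source = c("u1", "u2", "u3"),
                           target = c("gA", "gB", "u1"),
                           sign = c(1L, 1L, 1L))
  eg1 <- expand_reaction(m, rn, "Rz", layers = 1L)
  # u1/u2 joined as inputs; u3 (layer-2 regulator) not yet present
  expect_true(all(c("u1", "u2") %in% eg1$nodes))
  expect_false("u3" %in% eg1$nodes)
  expect_true(gmisnet:::bn_is_input(eg1, "u1"))
  eg2 <- expand_reaction(m, rn, "Rz", layers = 2L)
  expect_true("u3" %in% eg2$nodes)
  expect_equal(render_gpr(eg2$f[["u1"]]), "u3")
  # repeated construction is identical
  expect_identical(eg2, expand_reaction(m, rn, "Rz", layers = 2L))
})

test_that("expanding a reaction without a gene association is an error", {
  gem <- make_toy_gem("plain")
  expect_error(expand_reaction(gem$model, gem$regnet, "R_up", layers = 1L),
               "no gene association")
  expect_error(expand_reaction(gem$model, gem$regnet, "nope", layers = 1L),
               "not in model")
})
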