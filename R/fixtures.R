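## Self-contained toy fixtures with brute-forceable ground truth: a cyclic
## toggle-switch model, a 4-reaction toy metabolic model in three regulatory
## variants, seeded random Boolean networks for the oracle corpus, and a
## simulated dependency screen with planted essentiality.  Fixture scale is
## capped (<= 12 Boolean nodes, <= 6 metabolic genes) so every exhaustive
## oracle runs in seconds.

new_fixture_bundle <- function(model, regnet, ground_truth, expression = NULL,
                               scores = NULL) {
  structure(list(model = model, regnet = regnet, ground_truth = ground_truth,
                 expression = expression, scores = scores),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> model '", x$model$id, "', ", nrow(x$regnet),
      " regulatory edge(s)\n", sep = "")
  invisible(x)
}

#' Toggle-switch fixture
#'
#' A one-reaction model (target `R1`, GPR `g1`) whose gene is activated by
#' `r1`, itself locked in a mutual-repression toggle with `r2` (`r1`
#' represses `r2`, `r2` represses `r1`).  With 2 regulatory layers, the
#' eGPR has two attractors (toggle up / toggle down) and the minimal
#' marker-inactivating sets are exactly `{g1-}`, `{r1-}`, `{r2+}`; with 0
#' layers the ground truth collapses to `{g1-}`.
#'
#' @return A `fixture_bundle` with `ground_truth$intervention_sets`,
#'   `$gdict_rows`, `$layers`, `$kmax`.
#' @export
make_toggle_fixture <- function() {
  model <- metabolic_model(
    reactions = "R1", metabolites = character(0),
    S = matrix(0, 0, 1), lb = 0, ub = 10,
    gpr = list(R1 = "g1"), target = "R1", id = "toggle")
  regnet <- regulatory_network(
    source = c("r1", "r1", "r2"),
    target = c("g1", "r2", "r1"),
    sign = c(1L, -1L, -1L))
  gt <- list(
    layers = 2L, kmax = 3L,
    intervention_sets = list(
      intervention_set(KO = "g1"),
      intervention_set(KO = "r1"),
      intervention_set(KI = "r2")),
    gdict_rows = list(R1 = list(list(K = "g1", N = character(0)),
                                list(K = "r1", N = character(0)),
                                list(K = character(0), N = "r2"))),
    gmis = list(
      intervention_set(KO = "g1"),
      intervention_set(KO = "r1"),
      intervention_set(KI = "r2")))
  new_fixture_bundle(model, regnet, gt)
}

#' Toy metabolic model fixture
#'
#' Four irreversible reactions (bounds 0..10): an uptake producing `A`, two
#' parallel conversions `A -> B` (`R1` with GPR `g1 and g2`, `R2` with GPR
#' `g3`), and the target drain `R_bm: B ->`.  Both branches must be blocked
#' to cut the target.  Variants add regulation of `g3`: `"activator"` wires
#' `r3 -> g3 (+)`; `"repressor"` wires `r3 -> g3 (+)` and `r4 -| g3 (-)`
#' (so `g3 = r3 and not r4`), which makes the knock-in `r4+` an alternative
#' way to silence the `R2` branch.
#'
#' @param variant `"plain"`, `"activator"`, or `"repressor"`.
#' @return A `fixture_bundle`; `ground_truth$gmis` holds the gMIS list at
#'   `max_size = 2` (2, 4, and 6 sets respectively).
#' @export
make_toy_gem <- function(variant = c("plain", "activator", "repressor")) {
  variant <- match.arg(variant)
  rxns <- c("R_up", "R1", "R2", "R_bm")
  mets <- c("A", "B")
  S <- matrix(c(1, 0,   # R_up: -> A
                -1, 1,  # R1: A -> B
                -1, 1,  # R2: A -> B
                0, -1), # R_bm: B ->
              nrow = 2, ncol = 4, dimnames = list(mets, rxns))
  model <- metabolic_model(rxns, mets, S, lb = rep(0, 4), ub = rep(10, 4),
                           gpr = list(R1 = "g1 and g2", R2 = "g3"),
                           target = "R_bm", id = paste0("toy_gem_", variant))
  regnet <- switch(variant,
    plain = regulatory_network(),
    activator = regulatory_network("r3", "g3", 1L),
    repressor = regulatory_network(c("r3", "r4"), c("g3", "g3"), c(1L, -1L)))
  r1_rows <- list(list(K = "g1", N = character(0)), list(K = "g2", N = character(0)))
  r2_rows <- switch(variant,
    plain = list(list(K = "g3", N = character(0))),
    activator = list(list(K = "g3", N = character(0)),
                     list(K = "r3", N = character(0))),
    repressor = list(list(K = "g3", N = character(0)),
                     list(K = "r3", N = character(0)),
                     list(K = character(0), N = "r4")))
  gmis <- switch(variant,
    plain = list(intervention_set(KO = c("g1", "g3")),
                 intervention_set(KO = c("g2", "g3"))),
    activator = list(intervention_set(KO = c("g1", "g3")),
                     intervention_set(KO = c("g1", "r3")),
                     intervention_set(KO = c("g2", "g3")),
                     intervention_set(KO = c("g2", "r3"))),
    repressor = list(intervention_set(KO = c("g1", "g3")),
                     intervention_set(KO = c("g1", "r3")),
                     intervention_set(KO = "g1", KI = "r4"),
                     intervention_set(KO = c("g2", "g3")),
                     intervention_set(KO = c("g2", "r3")),
                     intervention_set(KO = "g2", KI = "r4")))
  gt <- list(layers = if (variant == "plain") 0L else 1L, kmax = 3L,
             max_size = 2L,
             gdict_rows = list(R1 = r1_rows, R2 = r2_rows),
             gmis = gmis)
  new_fixture_bundle(model, regnet, gt)
}

#' Seeded random Boolean network
#'
#' Each node draws 0..`max_indegree` distinct signed regulators (uniform
#' over nodes, self-loops allowed) and combines them with the standard
#' regulatory rule ([combine_regulators()]); nodes with no regulators are
#' free inputs.  Identical seeds give identical networks; the caller's RNG
#' state is untouched.
#'
#' @param n Number of nodes (>= 1).
#' @param max_indegree Maximum regulators per node (>= 1).
#' @param seed Integer seed (required).
#' @return A `boolean_network`.
#' @export
random_boolean_network <- function(n, max_indegree = 2L, seed) {
  if (n < 1L || max_indegree < 1L) stop2("need n >= 1 and max_indegree >= 1")
  if (missing(seed)) stop2("seed is required")
  with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    f <- stats::setNames(vector("list", n), nodes)
    for (v in nodes) {
      k <- sample(0:max_indegree, 1L)
      if (k == 0L) {
        f[[v]] <- bx_lit(v)
      } else {
        regs <- sample(nodes, k)
        signs <- sample(c(1L, -1L), k, replace = TRUE)
        f[[v]] <- combine_regulators(regs[signs > 0], regs[signs < 0])
      }
    }
    boolean_network(f)
  })
}

#' Simulated dependency screen with planted essentiality
#'
#' Builds, for a fixture bundle with ground-truth gMISs, an expression
#' matrix over the gMIS genes and a DepMap-style score matrix over the
#' knockout genes.  Per sample, one gMIS and one of its knockout members
#' are chosen (seeded) and the expression pattern is set so that member is
#' the unique highly expressed knockout gene and all knock-in members are
#' highly expressed; remaining context genes are random.  True essentiality
#' is then derived by the prediction rule itself, scores are set to -1
#' (essential) or 0, and a fraction `noise` of the labels is flipped across
#' the -0.6 DepMap cutoff.
#'
#' @param bundle A `fixture_bundle` with `ground_truth$gmis`.
#' @param n_samples Number of simulated cell lines (default 20).
#' @param noise Fraction of labels flipped in `[0, 1]` (default 0).
#' @param seed Integer seed (required).
#' @param cfg A `screening_config` (sets the high-expression threshold).
#' @return The bundle with `expression` (`expression_matrix`, high = 5, low
#'   = 0) and `scores` (`dependency_scores`, platform `"depmap"`) filled in.
#' @export
make_screen_fixture <- function(bundle, n_samples = 20L, noise = 0, seed,
                                cfg = screening_config()) {
  gmis <- bundle$ground_truth$gmis %||% stop2("bundle has no ground-truth gMIS list")
  if (missing(seed)) stop2("seed is required")
  if (noise < 0 || noise > 1) stop2("noise must be in [0, 1]")
  genes <- csort(unique(unlist(lapply(gmis, function(iv) c(iv$KO, iv$KI)), use.names = FALSE)))
  universe <- csort(unique(unlist(lapply(gmis, `[[`, "KO"), use.names = FALSE)))
  hi <- 5; lo <- 0
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    expr <- matrix(lo, length(genes), n_samples, dimnames = list(genes, samples))
    for (j in seq_len(n_samples)) {
      expr[, j] <- sample(c(lo, hi), length(genes), replace = TRUE)
      iv <- gmis[[1L + (j - 1L) %% length(gmis)]]
      if (length(iv$KO)) {
        pick <- iv$KO[[sample.int(length(iv$KO), 1L)]]
        expr[iv$KO, j] <- lo
        expr[pick, j] <- hi
      }
      if (length(iv$KI)) expr[iv$KI, j] <- hi
    }
    expr <- structure(expr, class = c("expression_matrix", class(expr)))
    truth <- predict_essential(gmis, expr, cfg)
    scores <- matrix(0, length(universe), n_samples, dimnames = list(universe, samples))
    for (j in seq_len(n_samples)) scores[truth[[samples[j]]]$gene, j] <- -1
    n_flip <- round(noise * length(scores))
    if (n_flip > 0L) {
      flip <- sample.int(length(scores), n_flip)
      scores[flip] <- ifelse(scores[flip] == -1, 0, -1)
    }
    scores <- structure(scores, class = c("dependency_scores", class(scores)),
                        platform = "depmap")
    new_fixture_bundle(bundle$model, bundle$regnet, bundle$ground_truth,
                       expression = expr, scores = scores)
  })
}

#' Materialize a fixture bundle as files
#'
#' Writes `model.json`, `model.sbml`, `regnet.tsv`, `ground_truth.json`,
#' and, when present, `expression.csv` and `scores.csv` into `dir`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_json(bundle$model, file.path(dir, "model.json"))
  write_model_sbml(bundle$model, file.path(dir, "model.sbml"))
  write_regulatory_network(bundle$regnet, file.path(dir, "regnet.tsv"))
  gt <- bundle$ground_truth
  out <- list(layers = gt$layers, kmax = gt$kmax,
              gdict = lapply(gt$gdict_rows, function(rows) {
                lapply(rows, function(row) list(K = as.list(row$K), N = as.list(row$N)))
              }),
              gmis = lapply(gt$gmis, function(iv) list(K = as.list(iv$KO), N = as.list(iv$KI))))
  if (!is.null(gt$max_size)) out$max_size <- gt$max_size
  jsonlite::write_json(out[corder(names(out))], file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$expression)) {
    write_matrix_csv(bundle$expression, file.path(dir, "expression.csv"))
  }
  if (!is.null(bundle$scores)) {
    write_matrix_csv(bundle$scores, file.path(dir, "scores.csv"))
  }
  invisible(dir)
}
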