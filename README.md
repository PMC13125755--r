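# gmisnet

Genetic Minimal Intervention Sets (gMISs) in genome-scale metabolic models
integrated with **cyclic** transcriptional regulatory networks.

## The problem

Constraint-based metabolic models predict which gene knockouts abolish a
target metabolic function (biomass production, a drain reaction, ...) through
genetic Minimal Cut Sets: inclusion-minimal gene sets whose loss makes the
target flux infeasible. Classical gMCS analysis reads only the
Gene–Protein–Reaction (GPR) rules, so it is blind to transcriptional
regulation — and methods that do add regulation usually flatten it into
acyclic chains, discarding the feedback loops that dominate real regulatory
networks. `gmisnet` keeps the cycles. It targets systems biologists who want
regulation-aware synthetic-lethality predictions (e.g. against CRISPR
dependency screens) on models they can fully verify.

## The method

For each reaction `r` with GPR rule `G_r`:

1. **Extended GPR (eGPR).** Starting from the Boolean network
   `marker_r = G_r(genes)` with all genes as free inputs, regulators are
   wired in layer by layer (layer 1 = direct regulators, layer `k` =
   regulators at depth `k`), using the update rule
   `g = OR(activators) AND NOT OR(repressors)`. Regulators already present
   are wired back, so feedback cycles — including self-loops — are retained.
   After each per-gene expansion, the marker must stay attainable in some
   attractor; otherwise that expansion is reverted and the gene stays a free
   input.
2. **Attractors = minimal trap spaces.** A trap space is a subcube of
   Boolean states closed under the update functions; the inclusion-minimal
   ones serve as the attractors, independent of any update scheme.
   `gmisnet` computes them by a prime-implicant-supported search and ships
   an exhaustive `3^n`-subcube oracle that the fast path must reproduce
   exactly.
3. **GDict.** Per reaction, all inclusion-minimal signed intervention rows
   `(K = knockouts, N = knock-ins)` that fix the marker to 0 in *every*
   attractor (marker reprogramming with an inactivation marker), rendered on
   demand as binary constraint matrices `G` and `F`.
4. **gMIS enumeration.** An intervention set blocks reaction `r` when some
   GDict row of `r` is fully selected. A set is a gMIS when the LP
   `max v_target  s.t.  S·v = 0, lb ≤ v ≤ ub, v_r = 0 ∀ blocked r`
   has optimum ≤ `flux_tol`, and no proper subset does. Enumeration runs by
   cardinality level with superset-exclusion cuts and LP memoization.
5. **Screening.** An adaptation post-check discards gMISs whose single
   knockouts force partner genes into the opposite state in every attractor;
   per-sample essential genes are then predicted from expression (a knockout
   gene is called when it is the unique highly expressed knockout member and
   all knock-in members are expressed) and scored against dependency screens
   (DepMap essential iff score ≤ −0.6; Project Score essential iff
   score > 0) with the Matthews correlation coefficient
   `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.

Every stage has a brute-force oracle (`trap_spaces_exhaustive`,
`inactivating_sets_exhaustive`, `gmis_exhaustive`, `gene_mcs_from_gpr`) and
self-contained toy fixtures with hand-derivable ground truth.

## Worked example

The bundled "repressor" toy model has two routes to the biomass drain
`R_bm`: `R1` (GPR `g1 and g2`) and `R2` (GPR `g3`), with `g3` activated by
`r3` and repressed by `r4`:

```r
library(gmisnet)
bundle <- make_toy_gem("repressor")
expand_reaction(bundle$model, bundle$regnet, "R2", layers = 1)
#> <egpr_network> marker R2, 4 nodes, 1 layer(s)
#>   [0] R2 <- g3
#>   [0] g3 <- r3 and not r4
#>   [1] r3 <- r3
#>   [1] r4 <- r4

gd <- build_gdict(bundle$model, bundle$regnet, layers = 1)
gmis <- enumerate_gmis(bundle$model, gd, solver_config(max_size = 2))
for (g in gmis) print(g)
#> <gmis> {g1-;g3-} blocks {R1, R2}
#> <gmis> {g1-;r3-} blocks {R1, R2}
#> <gmis> {g1-;r4+} blocks {R1, R2}
#> <gmis> {g2-;g3-} blocks {R1, R2}
#> <gmis> {g2-;r3-} blocks {R1, R2}
#> <gmis> {g2-;r4+} blocks {R1, R2}
```

Each line is one minimal intervention set (`-` knockout, `+` knock-in) with
the reactions it blocks: cutting the `R1` branch needs `g1-` or `g2-`, and
the `R2` branch falls to `g3-`, to losing its activator (`r3-`), or to
forcing its repressor on (`r4+`) — the knock-in route only regulation can
reveal. Scoring a simulated noiseless dependency screen recovers the planted
essentiality perfectly:

```r
scr  <- make_screen_fixture(bundle, n_samples = 6, noise = 0, seed = 42)
pred <- predict_essential(gmis, scr$expression)
evaluate_predictions(pred, label_dependencies(scr$scores),
                     universe = rownames(scr$scores))
#>   sample TP FP TN FN MCC
#> 1    S01  1  0  3  0   1
#> ...
#> pooled MCC: 1
```

A command-line interface mirrors the R API stage by stage
(`exec/gmisnet fixtures | build-gdict | compute-gmis | predict | evaluate`);
see `exec/gmisnet --help`.

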