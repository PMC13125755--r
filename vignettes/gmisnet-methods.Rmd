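---
title: "Methods: regulation-aware minimal intervention sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulation-aware minimal intervention sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmisnet)
```

## Overview

`gmisnet` computes genetic Minimal Intervention Sets (gMISs): inclusion-
minimal combinations of gene knockouts (`g-`) and knock-ins (`g+`) that make
a target reaction of a constraint-based metabolic model unable to carry
flux, when the Gene–Protein–Reaction (GPR) rules are extended with a signed,
possibly cyclic, transcriptional regulatory network. This vignette explains
the model, the algorithmic and numerical choices, and what the bundled
synthetic fixtures do and do not establish.

## The model and its assumptions

**Metabolic layer.** A model is `(S, lb, ub, GPR, target)`: stoichiometry
`S` (metabolites × reactions), flux bounds, per-reaction Boolean GPR rules
over gene identifiers, and a target reaction. Blocking a reaction means
pinning its flux to zero; the target is *blocked* when
`max v_target s.t. S v = 0, lb ≤ v ≤ ub, v_r = 0 for blocked r` falls below
a tolerance. Reversible reactions are handled by their negative lower
bounds directly; reactions are never split. Reactions without a GPR are
genetically unblockable and contribute nothing.

**Regulatory layer.** The regulatory network is a list of signed edges
(activation `+1`, repression `-1`). Edge semantics are deliberately
threshold-free: a regulated gene follows
`OR(activators) AND NOT OR(repressors)`. This combination rule is a
standard convention, not the only defensible one, so it is isolated in
`combine_regulators()` and stated here as a design choice. Conflicting-sign
edge pairs are retained as two edges (and flagged on load), which under the
rule above lets the repressor dominate.

**Dynamics.** Each reaction's extended GPR (eGPR) is a Boolean network:
the reaction marker computes the GPR over its genes; regulated genes
compute the combination rule over their regulators; everything else is a
free input (modelled as a self-referential function so attractors may leave
it unfixed). Attractors are identified with **minimal trap spaces** —
inclusion-minimal subcubes closed under the update functions. This choice
makes the dynamics update-scheme-independent, matches the most-permissive
semantics of the Boolean-reprogramming literature, and — critically for a
verifiable package — is exhaustively checkable at small `n`.

## Layered expansion and the consistency check

Expansion proceeds layer by layer (layer 1 = direct regulators of GPR
genes, layer `k` = depth-`k` regulators), processing genes within a layer in
lexicographic order so the construction is deterministic. A regulator added
in layer `k` whose own regulators are all already present is wired back
immediately; this is what closes feedback cycles such as the bundled
toggle-switch fixture. Genes whose regulators lie beyond the configured
horizon stay free inputs.

Wiring in regulation can make the marker unattainable (e.g. a lone negative
self-loop under the strict reading below). After each per-gene expansion the
package therefore checks that some minimal trap space leaves the marker
attainable, and reverts just that gene's expansion otherwise (logged, gene
stays an input). Two open points are resolved as explicit options:

* **Reachability sense.** "Attainable" defaults to *permissive* (marker not
  fixed to 0: fixed to 1 or oscillating counts), with a *strict* option
  (marker fixed to 1 in some attractor). The two differ exactly on
  oscillating markers; the negative self-loop test pins both behaviors.
* **Revert granularity.** Rollback is per-gene, not per-layer, maximizing
  retained regulation while staying deterministic under the lexicographic
  processing order.

## Trap spaces, reprogramming, and the oracles

A subcube is a trap space iff every fixed literal `(v = c)` is *supported*:
some prime implicant of `[f_v = c]` lies entirely inside the subcube's
literal set. Minimal trap spaces are therefore the maximal consistent
supported literal sets, and `minimal_trap_spaces()` enumerates them by a
branch-and-resolve search over node states (fix to 0, fix to 1, or leave
free) that discharges support obligations by branching over prime
implicants. Free inputs and constant nodes skip the "free" branch — a leaf
leaving them free can always be extended, hence is never maximal.

The independent reference is `trap_spaces_exhaustive()`: a vectorized scan
of all `3^n` subcubes for closure, followed by an inclusion-minimality
filter. The two routes share no code beyond expression evaluation, and
their exact agreement on seeded random-network corpora is the package's
first acceptance property.

`minimal_inactivating_sets()` solves marker reprogramming for the
inactivation marker: all minimal signed perturbation sets (≤ `kmax`) whose
application leaves *every* minimal trap space with the marker fixed to 0.
A trap space with the marker oscillating counts as *not* inactivated. The
search is breadth-first by cardinality with superset skipping, so results
are minimal by construction; `inactivating_sets_exhaustive()` re-derives
them by testing every signed subset against the exhaustive trap-space scan.

## GDict and gMIS enumeration

`build_gdict()` maps each reaction with a non-constant GPR to its minimal
intervention rows; rows per reaction form an antichain and rows are kept
per-reaction (never merged across reactions, so a row's provenance stays
unambiguous). The result is independent of the worker count — parallelism
is a contract, not a semantics.

`enumerate_gmis()` lifts rows to target-blocking sets. The feasibility
check is a dense two-phase primal simplex written for this package
(`lp_bounded_max()`), with Bland's anti-cycling rule; flux-balance LPs at
fixture scale are tiny, and the solver is pinned by a vertex-enumeration
oracle in the tests. Enumeration proceeds by cardinality level over the
signed candidate pool (genes in any knockout row as `g-`, genes in any
knock-in row as `g+`), with two cuts: supersets of recorded solutions are
skipped, and LP outcomes are memoized on the induced blocked-reaction set —
distinct selections that block the same reactions are solved once. With
levels exhausted in order, recorded sets are inclusion-minimal without a
trimming pass. `gmis_exhaustive()` is the unpruned reference.

Two published-method ambiguities are resolved as follows and exposed:
the maximal perturbation size is a parameter (`kmax`, default 3) rather
than a guess, and target blocking means strict LP infeasibility
(`≤ flux_tol` after normalizing the target's upper bound to 1) rather than
a fraction-of-wild-type growth threshold.

## Screening

`adaptation_check()` applies each knockout member of a gMIS alone and asks
for at least one attractor in which no other knockout member is forced on
and no knock-in member forced off; any failing member flags the whole set.
The direction — perturb each knockout singly, observe the partners — is an
interpretation choice documented here; the two 2-node wiring motifs
(antagonistic `g2 = not g1` fails, co-activated `g2 = g1` passes) fix the
implemented semantics in the tests.

`predict_essential()` calls gene `g` essential in a sample when some gMIS
has `g` as its unique highly expressed knockout member and all knock-in
members highly expressed — the intervention then degenerates to the single
knockdown of `g` in that context. "Highly expressed" is a configurable
binarization (`expr > expr_high_threshold`, default 1.0 in the matrix's own
units) because real datasets differ in scale. Dependency labels use the
published cutoffs verbatim: DepMap essential iff score ≤ −0.6 (boundary
essential), Project Score essential iff score > 0 (boundary non-essential).
Per-sample Matthews correlation uses the zero-denominator → 0 convention;
a pooled MCC over summed counts accompanies the per-sample table, which is
the input a downstream significance analysis would consume (such modelling
is out of scope here).

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `layers` | 1 | regulatory expansion depth; 0 = classical GPR-only behavior |
| `kmax` | 3 | max intervention-row size per reaction (search is exponential in it) |
| `max_size` | 3 | max gMIS cardinality |
| `max_solutions` | 100 | enumeration cap |
| `flux_tol` | 1e-6 | LP feasibility tolerance after target-bound normalization |
| `sense` | permissive | marker-attainability reading during expansion |
| `expr_high_threshold` | 1.0 | expression binarization (dataset units) |
| DepMap / Project Score cutoffs | −0.6 / 0 | essentiality labels, applied as printed |

Canonical orderings (node lists, trap spaces, intervention sets by size then
lexicographic knockouts then knock-ins) use C-collation string order, so
outputs are byte-stable across locales; JSON artifacts are written with
sorted keys for diffability.

## What the synthetic fixtures emulate — and what they do not

The fixtures are designed for *verifiability*, not realism: every ground
truth is re-derivable by the exhaustive oracles in seconds. The toggle
fixture plants a bistable feedback loop upstream of a reaction — the
smallest structure where cyclic integration changes the answer (it adds
`r1-` and `r2+` to the GPR-only `g1-`). The toy metabolic model plants two
parallel routes to the target so every gMIS must combine interventions
across branches, with variants that add an activator and a repressor (the
latter introducing genuine knock-in solutions). The simulated screen plants
essentiality *by the prediction rule itself* and flips a chosen fraction of
labels, so noiseless recovery must be exact (pooled MCC 1.0) and full label
inversion must flip the sign.

Scales used throughout tests and the acceptance script: random Boolean
networks of 4–10 nodes with in-degree ≤ 2 (100 networks for trap-space
agreement, 30 for reprogramming agreement at `kmax` 2–3), toy models with
≤ 6 genes, screens with 20 samples. These sizes keep the `3^n` and
signed-subset oracles exact.

Consequently, passing fixtures shows correctness of the algorithms, not
biological performance: real regulatory networks are orders of magnitude
larger, noisy, and incomplete; real expression calls for dataset-specific
binarization; real screens measure single knockouts only, so knock-in
predictions and multi-gene interactions remain unvalidated by construction.

## Known limitations

* Trap-space enumeration is exact but exponential in the worst case; it is
  intended for eGPR networks of per-reaction scale (tens of nodes), not for
  whole-network attractor landscapes.
* The GPR SBML reader/writer supports a minimal SBML L3V1 + fbc subset;
  Boolean `NOT` cannot be expressed in fbc and is only available through
  the JSON model dialect.
* Gene identifiers are opaque strings; no cross-referencing between model,
  network, and screen namespaces is attempted.
* The regulator combination rule is a stated convention; alternative
  threshold or majority rules would change eGPR dynamics and are not
  implemented.
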