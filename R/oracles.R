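## Exhaustive brute-force oracles.  These deliberately share no machinery
## with the production algorithms they check: trap spaces are found by a
## flat scan over all 3^n subcubes, intervention sets by testing every
## signed subset.  They are only usable at small n but are the ground truth
## the fast implementations must reproduce exactly.

#' Exhaustive minimal trap spaces (brute-force reference)
#'
#' Scans all `3^n` subcubes for closure under the update functions and keeps
#' the inclusion-minimal closed ones.  Independent of
#' [minimal_trap_spaces()]; intended for testing at `n <= 12`.
#'
#' @param bn A `boolean_network` with at most 12 nodes.
#' @return Same representation and canonical order as
#'   [minimal_trap_spaces()].
#' @export
trap_spaces_exhaustive <- function(bn) {
  nodes <- bn$nodes
  n <- length(nodes)
  if (n > 12L) stop2("exhaustive scan limited to 12 nodes (got ", n, ")")
  n_sub <- 3L^n
  ## all subcubes; value 2 encodes "free"
  states <- matrix(0L, n_sub, n)
  rep_each <- 1L
  for (j in seq_len(n)) {
    states[, j] <- rep(rep(0:2, each = rep_each), length.out = n_sub)
    rep_each <- rep_each * 3L
  }
  ok <- rep(TRUE, n_sub)
  for (j in seq_len(n)) {
    v <- nodes[[j]]
    tte <- expr_tt(bn$f[[v]])
    vars <- tte$vars
    k <- length(vars)
    ncomb <- 3L^k
    can0 <- can1 <- logical(ncomb)
    if (k == 0L) {
      val <- tte$tt[1L]
      can1[] <- val == 1L
      can0[] <- val == 0L
    } else {
      pow2 <- bitwShiftL(1L, seq_len(k) - 1L)
      for (ci in seq_len(ncomb) - 1L) {
        d <- (ci %/% 3L^(seq_len(k) - 1L)) %% 3L
        free <- which(d == 2L)
        idx <- 1L + sum(pow2[d == 1L])
        for (fj in free) idx <- c(idx, idx + pow2[fj])
        vals <- tte$tt[idx]
        can1[ci + 1L] <- any(vals == 1L)
        can0[ci + 1L] <- any(vals == 0L)
      }
    }
    ci <- rep(0L, n_sub)
    if (k > 0L) {
      vcols <- match(vars, nodes)
      for (m in seq_len(k)) ci <- ci + states[, vcols[m]] * 3L^(m - 1L)
    }
    viol <- (states[, j] == 0L & can1[ci + 1L]) | (states[, j] == 1L & can0[ci + 1L])
    ok <- ok & !viol
  }
  closed <- which(ok)
  if (!length(closed)) return(list())
  sub <- states[closed, , drop = FALSE]
  fixed_n <- rowSums(sub != 2L)
  ord <- order(-fixed_n)
  sub <- sub[ord, , drop = FALSE]
  pow2 <- bitwShiftL(1L, seq_len(n) - 1L)
  fmask <- as.integer((sub != 2L) %*% pow2)
  vmask <- as.integer((sub == 1L) %*% pow2)
  ## most-fixed first: a closed subcube is minimal iff it strictly contains
  ## no already-accepted minimal one
  acc_f <- integer(0)
  acc_v <- integer(0)
  keep <- integer(0)
  for (i in seq_along(fmask)) {
    fs <- fmask[i]; vs <- vmask[i]
    dominated <- FALSE
    if (length(acc_f)) {
      inside <- bitwAnd(acc_f, fs) == fs & bitwAnd(acc_v, fs) == bitwAnd(vs, fs) &
        !(acc_f == fs & acc_v == vs)
      dominated <- any(inside)
    }
    if (!dominated) {
      acc_f <- c(acc_f, fs)
      acc_v <- c(acc_v, vs)
      keep <- c(keep, i)
    }
  }
  out <- lapply(keep, function(i) {
    s <- sub[i, ]
    s[s == 2L] <- NA_integer_
    names(s) <- nodes
    s
  })
  out[corder(vapply(out, subcube_key, ""))]
}

#' Exhaustive minimal inactivating sets (brute-force reference)
#'
#' Tests every signed perturbation subset of size at most `kmax` with
#' [trap_spaces_exhaustive()] and keeps the inclusion-minimal sets whose
#' every minimal trap space fixes `marker` to 0.  Independent of
#' [minimal_inactivating_sets()].
#'
#' @inheritParams minimal_inactivating_sets
#' @return List of `intervention_set` in canonical order.
#' @export
inactivating_sets_exhaustive <- function(bn, marker, kmax = 3L,
                                         candidates = setdiff(bn$nodes, marker)) {
  if (!marker %in% bn$nodes) stop2("marker node '", marker, "' not in network")
  candidates <- csort(setdiff(candidates, marker))
  inactive <- function(iv) {
    ts <- trap_spaces_exhaustive(apply_perturbation(bn, iv))
    all(vapply(ts, function(s) !is.na(s[[marker]]) && s[[marker]] == 0L, logical(1)))
  }
  hits <- list()
  for (size in seq_len(min(kmax, length(candidates)))) {
    for (genes in utils::combn(candidates, size, simplify = FALSE)) {
      for (mask in 0:(2L^size - 1L)) {
        ki_sel <- bitwAnd(bitwShiftR(mask, seq_len(size) - 1L), 1L) == 1L
        iv <- intervention_set(KO = genes[!ki_sel], KI = genes[ki_sel])
        if (inactive(iv)) hits[[length(hits) + 1L]] <- iv
      }
    }
  }
  ## post-filter to the antichain of inclusion-minimal sets
  keep <- vapply(seq_along(hits), function(i) {
    !any(vapply(seq_along(hits), function(j) {
      i != j && iv_size(hits[[j]]) < iv_size(hits[[i]]) && iv_subset(hits[[j]], hits[[i]])
    }, logical(1)))
  }, logical(1))
  sort_intervention_sets(hits[keep])
}

#' Exhaustive gMIS enumeration (brute-force reference)
#'
#' Tests every signed subset of the GDict's candidate genes up to
#' `cfg$max_size` with [blocks_target()] and keeps the inclusion-minimal
#' blocking sets.  Independent of the pruned search in [enumerate_gmis()].
#'
#' @inheritParams enumerate_gmis
#' @return List of `gmis` objects in canonical order.
#' @export
gmis_exhaustive <- function(model, gdict, cfg = solver_config()) {
  pools <- gdict_candidate_pools(gdict)
  genes <- csort(union(pools$ko, pools$ki))
  hits <- list()
  for (size in seq_len(min(cfg$max_size, length(genes)))) {
    for (sel in utils::combn(genes, size, simplify = FALSE)) {
      for (mask in 0:(2L^size - 1L)) {
        ki_sel <- bitwAnd(bitwShiftR(mask, seq_len(size) - 1L), 1L) == 1L
        ko <- sel[!ki_sel]
        ki <- sel[ki_sel]
        if (!all(ko %in% pools$ko) || !all(ki %in% pools$ki)) next
        iv <- intervention_set(KO = ko, KI = ki)
        if (blocks_target(model, gdict, iv, cfg)) hits[[length(hits) + 1L]] <- iv
      }
    }
  }
  keep <- vapply(seq_along(hits), function(i) {
    !any(vapply(seq_along(hits), function(j) {
      i != j && iv_size(hits[[j]]) < iv_size(hits[[i]]) && iv_subset(hits[[j]], hits[[i]])
    }, logical(1)))
  }, logical(1))
  ivs <- sort_intervention_sets(hits[keep])
  lapply(ivs, function(iv) new_gmis(iv, blocked_reactions(gdict, iv)))
}

#' Classical gene-level minimal cut sets from GPR prime implicants
#'
#' Independent route for the zero-regulatory-layer case: builds the Boolean
#' target-feasibility function over the model's GPR genes by direct flux
#' evaluation at every gene on/off assignment, extracts its prime implicants,
#' and enumerates their minimal transversals (hitting sets).  These are the
#' classical knockout-only gMCSs that the full pipeline must reproduce when
#' run with 0 regulatory layers.
#'
#' @param model A `metabolic_model` whose GPR genes number at most 12.
#' @param max_size Largest cut-set size to report.
#' @param flux_tol Feasibility tolerance on the (normalized) target flux.
#' @return List of sorted character vectors (gene knockout sets) in canonical
#'   order.
#' @export
gene_mcs_from_gpr <- function(model, max_size = 3L, flux_tol = 1e-6) {
  genes <- model_genes(model)
  k <- length(genes)
  if (k > 12L) stop2("prime-implicant route limited to 12 genes")
  feasible <- integer(bitwShiftL(1L, k))
  env <- integer(k)
  names(env) <- genes
  for (i in seq_along(feasible) - 1L) {
    for (j in seq_len(k)) env[[j]] <- bitwAnd(bitwShiftR(i, j - 1L), 1L)
    off <- vapply(model$reactions, function(r) {
      e <- model$gpr[[r]]
      !is.null(e) && eval_expr(e, env) == 0L
    }, logical(1))
    opt <- lp_max_target(model, model$reactions[off])
    feasible[i + 1L] <- as.integer(opt > flux_tol)
  }
  pis <- prime_implicants_tt(feasible, genes, 1L)
  ## a cut set must hit the positive literals of every prime implicant
  pos <- lapply(pis, function(p) names(p)[p == 1L])
  if (any(lengths(pos) == 0L)) return(list())   # feasible with all genes off
  hits <- list()
  for (size in seq_len(min(max_size, k))) {
    for (sel in utils::combn(genes, size, simplify = FALSE)) {
      if (any(vapply(hits, function(h) all(h %in% sel), logical(1)))) next
      if (all(vapply(pos, function(pp) any(pp %in% sel), logical(1)))) {
        hits[[length(hits) + 1L]] <- sel
      }
    }
  }
  hits[corder(vapply(hits, function(h) sprintf("%03d|%s", length(h), paste(h, collapse = ",")), ""))]
}
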