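## gMIS enumeration: minimal signed gene-intervention sets whose induced
## reaction blockings (via the GDict rows) make the target reaction
## infeasible under flux balance.  Feasibility is a plain LP (max target
## flux subject to S v = 0 and bounds, blocked reactions pinned to zero);
## enumeration is a cardinality-levelled search over signed candidate
## interventions with superset-exclusion cuts and LP memoization keyed on
## the induced blocked-reaction set.

#' Solver configuration
#'
#' @param max_size Largest intervention-set size to enumerate (default 3).
#' @param max_solutions Stop after this many gMISs (default 100).
#' @param flux_tol Feasibility tolerance on the LP optimum after the target
#'   upper bound is normalized to 1 (default 1e-6), making the test
#'   scale-free.
#' @param lp_backend LP backend token; `"simplex"` (the package's dense
#'   two-phase simplex) is the only backend.
#' @return A `solver_config`.
#' @export
solver_config <- function(max_size = 3L, max_solutions = 100L, flux_tol = 1e-6,
                          lp_backend = "simplex") {
  if (max_size < 1L) stop2("max_size must be >= 1")
  if (flux_tol <= 0) stop2("flux_tol must be > 0")
  if (!identical(lp_backend, "simplex")) stop2("unknown lp_backend '", lp_backend, "'")
  structure(list(max_size = as.integer(max_size),
                 max_solutions = as.integer(max_solutions),
                 flux_tol = as.numeric(flux_tol), lp_backend = lp_backend),
            class = "solver_config")
}

new_gmis <- function(iv, blocked) {
  structure(list(interventions = iv, blocked_reactions = csort(blocked)), class = "gmis")
}

#' @export
print.gmis <- function(x, ...) {
  cat("<gmis> ", iv_label(x$interventions), " blocks {",
      paste(x$blocked_reactions, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Reactions blocked by an intervention set
#'
#' A reaction is blocked when some GDict row of that reaction has its whole
#' knockout set within `iv$KO` and its whole knock-in set within `iv$KI`.
#'
#' @param gdict A `gdict`.
#' @param iv An `intervention_set`.
#' @return Sorted character vector of reaction ids.
#' @export
blocked_reactions <- function(gdict, iv) {
  hit <- vapply(names(gdict$rows), function(r) {
    for (row in gdict$rows[[r]]) {
      if (all(row$K %in% iv$KO) && all(row$N %in% iv$KI)) return(TRUE)
    }
    FALSE
  }, logical(1))
  csort(names(gdict$rows)[hit])
}

## Maximum target flux with the given reactions pinned to zero, after
## normalizing all bounds by the target upper bound.  Returns 0 when the
## LP is infeasible (no steady-state flux distribution at all).
lp_max_target <- function(model, blocked = character()) {
  target <- model$target
  if (model$ub[[target]] <= 0) return(0)
  if (target %in% blocked) return(0)
  scale <- model$ub[[target]]
  lb <- model$lb / scale
  ub <- model$ub / scale
  keep <- setdiff(model$reactions, blocked)
  ## a blocked reaction that cannot carry zero flux makes the whole model
  ## infeasible
  drop <- setdiff(model$reactions, keep)
  if (any(lb[drop] > 0 | ub[drop] < 0)) return(0)
  lbk <- lb[keep]
  ubk <- ub[keep]
  obj <- as.numeric(keep == target)
  ## shift x = v - lb so 0 <= x <= ub - lb
  Sk <- model$S[, keep, drop = FALSE]
  b <- if (nrow(Sk) > 0L) as.numeric(-Sk %*% lbk) else numeric(0)
  sol <- lp_bounded_max(obj, Sk, b, ubk - lbk)
  if (sol$status == "infeasible") return(0)
  if (sol$status != "optimal") stop2("LP solver failed with status '", sol$status,
                                     "'; model '", model$id, "'")
  as.numeric(sol$value + lbk[[target]])
}

#' Does an intervention set block the target reaction?
#'
#' TRUE iff the LP `max v_target` subject to `S v = 0`, `lb <= v <= ub`,
#' `v_r = 0` for every reaction blocked by `iv` (see [blocked_reactions()])
#' has an optimum at most `cfg$flux_tol` (bounds normalized so the target
#' upper bound is 1).
#'
#' @param model A `metabolic_model` with `ub[target] > 0`.
#' @param gdict A `gdict`.
#' @param iv An `intervention_set`.
#' @param cfg A `solver_config`.
#' @return Logical.
#' @export
blocks_target <- function(model, gdict, iv, cfg = solver_config()) {
  if (model$ub[[model$target]] <= 0) stop2("target reaction must have ub > 0")
  lp_max_target(model, blocked_reactions(gdict, iv)) <= cfg$flux_tol
}

#' Enumerate genetic minimal intervention sets
#'
#' Finds all inclusion-minimal signed intervention sets of size at most
#' `cfg$max_size` that block the target reaction ([blocks_target()]), up to
#' `cfg$max_solutions`, in canonical (size, lexicographic KO, lexicographic
#' KI) order.  Candidates are the genes occurring in any GDict knockout row
#' (as knockouts) or knock-in row (as knock-ins).  The search proceeds by
#' cardinality level with two cuts: supersets of recorded solutions are
#' excluded, and LP feasibility results are memoized on the induced
#' blocked-reaction set, so selections inducing the same blockings are
#' solved once.
#'
#' @inheritParams blocks_target
#' @return List of `gmis` objects (empty when the target is not blockable
#'   within `max_size`).
#' @seealso [gmis_exhaustive()] for the brute-force reference.
#' @export
enumerate_gmis <- function(model, gdict, cfg = solver_config()) {
  if (model$ub[[model$target]] <= 0) stop2("target reaction must have ub > 0")
  pools <- gdict_candidate_pools(gdict)
  genes <- csort(union(pools$ko, pools$ki))
  if (!length(genes)) return(list())
  found <- list()
  lp_cache <- new.env(parent = emptyenv())
  blocks_memo <- function(iv) {
    blocked <- blocked_reactions(gdict, iv)
    key <- paste(blocked, collapse = ",")
    hit <- lp_cache[[key]]
    if (is.null(hit)) {
      hit <- lp_max_target(model, blocked) <= cfg$flux_tol
      lp_cache[[key]] <- hit
    }
    hit
  }
  for (size in seq_len(min(cfg$max_size, length(genes)))) {
    if (length(found) >= cfg$max_solutions) break
    for (sel in utils::combn(genes, size, simplify = FALSE)) {
      if (length(found) >= cfg$max_solutions) break
      for (mask in 0:(2L^size - 1L)) {
        ki_sel <- bitwAnd(bitwShiftR(mask, seq_len(size) - 1L), 1L) == 1L
        ko <- sel[!ki_sel]
        ki <- sel[ki_sel]
        if (!all(ko %in% pools$ko) || !all(ki %in% pools$ki)) next
        iv <- intervention_set(KO = ko, KI = ki)
        if (any(vapply(found, function(g) iv_subset(g$interventions, iv), logical(1)))) next
        if (blocks_memo(iv)) {
          found[[length(found) + 1L]] <- new_gmis(iv, blocked_reactions(gdict, iv))
          if (length(found) >= cfg$max_solutions) break
        }
      }
    }
  }
  ords <- corder(vapply(found, function(g) iv_sort_key(g$interventions), ""))
  found[ords]
}

#' Write gMISs as TSV
#'
#' Columns: rank, KO genes (";"-joined), KI genes, blocked reactions.
#'
#' @param gmis_list List of `gmis`.
#' @param path Output path.
#' @export
write_gmis_tsv <- function(gmis_list, path) {
  df <- data.frame(
    rank = seq_along(gmis_list),
    KO = vapply(gmis_list, function(g) paste(g$interventions$KO, collapse = ";"), ""),
    KI = vapply(gmis_list, function(g) paste(g$interventions$KI, collapse = ";"), ""),
    blocked_reactions = vapply(gmis_list, function(g) paste(g$blocked_reactions, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gmis_tsv
#' @export
write_gmis_json <- function(gmis_list, path) {
  obj <- lapply(gmis_list, function(g) {
    list(KO = as.list(g$interventions$KO), KI = as.list(g$interventions$KI),
         blocked_reactions = as.list(g$blocked_reactions))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
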