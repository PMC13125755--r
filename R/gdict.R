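## GDict assembly: for each reaction, the minimal intervention rows that
## inactivate it in its extended GPR network, rendered on demand as the
## binary G (knockout) / F (knock-in) matrices consumed by the solver.

new_gdict <- function(rows, provenance = list()) {
  for (r in names(rows)) {
    for (row in rows[[r]]) {
      if (length(intersect(row$K, row$N))) {
        stop2("GDict row of '", r, "' has gene(s) in both K and N")
      }
    }
  }
  structure(list(rows = rows, provenance = provenance), class = "gdict")
}

#' @export
print.gdict <- function(x, ...) {
  cat("<gdict> ", length(x$rows), " reaction(s), ",
      sum(lengths(x$rows)), " intervention row(s)\n", sep = "")
  invisible(x)
}

#' Build the GDict of a model
#'
#' For every reaction with a non-constant GPR: expand its extended GPR
#' network to the requested regulatory depth ([expand_reaction()]), then
#' enumerate the minimal intervention rows that fix the reaction marker to 0
#' in every attractor ([minimal_inactivating_sets()]).  Reactions whose
#' marker is unattainable even unperturbed get an empty row list and a log
#' entry; reactions with no gene association produce no rows (they can never
#' be blocked genetically).
#'
#' The result is identical for any `workers` count; with `workers > 1`
#' reactions are processed in parallel via forked workers where available.
#'
#' @param model A `metabolic_model`.
#' @param regnet A `regulatory_network`.
#' @param layers Number of regulatory layers (0 = pure GPR behavior).
#' @param kmax Maximum intervention-row size per reaction.
#' @param workers Worker processes (>= 1).
#' @param sense Reachability sense, see [check_target_reachable()].
#' @return A `gdict`: per-reaction ordered lists of `list(K=, N=)` rows plus
#'   provenance (layers, kmax, model id); expansion logs in
#'   `attr(, "expansion_log")`.
#' @export
build_gdict <- function(model, regnet, layers = 1L, kmax = 3L, workers = 1L,
                        sense = c("permissive", "strict")) {
  sense <- match.arg(sense)
  if (workers < 1L) stop2("workers must be >= 1")
  rxns <- model$reactions[vapply(model$reactions, function(r) {
    g <- model$gpr[[r]]
    !is.null(g) && !is_const_expr(g)
  }, logical(1))]

  one <- function(r) {
    eg <- expand_reaction(model, regnet, r, layers = layers, sense = sense)
    if (!check_target_reachable(eg, eg$marker, sense)) {
      return(list(rows = list(), log = rbind(
        eg$log, data.frame(gene = eg$marker, layer = 0L, action = "marker_unreachable",
                           stringsAsFactors = FALSE))))
    }
    ivs <- minimal_inactivating_sets(eg, eg$marker, kmax = kmax)
    list(rows = lapply(ivs, function(iv) list(K = iv$KO, N = iv$KI)), log = eg$log)
  }

  use_fork <- workers > 1L && .Platform$OS.type != "windows"
  res <- if (use_fork) {
    parallel::mclapply(rxns, one, mc.cores = workers)
  } else {
    lapply(rxns, one)
  }
  for (x in res) if (inherits(x, "try-error")) stop2(attr(x, "condition")$message)
  names(res) <- rxns

  logs <- do.call(rbind, c(list(data.frame(reaction = character(), gene = character(),
                                           layer = integer(), action = character(),
                                           stringsAsFactors = FALSE)),
                           lapply(rxns, function(r) {
                             lg <- res[[r]]$log
                             if (!nrow(lg)) return(NULL)
                             cbind(reaction = r, lg)
                           })))
  gd <- new_gdict(lapply(res, `[[`, "rows"),
                  provenance = list(layers = as.integer(layers), kmax = as.integer(kmax),
                                    model_id = model$id))
  attr(gd, "expansion_log") <- logs
  gd
}

#' All genes occurring in a GDict
#' @param gdict A `gdict`.
#' @return Sorted character vector.
#' @export
gdict_genes <- function(gdict) {
  csort(unique(unlist(lapply(gdict$rows, function(rows) {
    unlist(lapply(rows, function(row) c(row$K, row$N)), use.names = FALSE)
  }), use.names = FALSE)))
}

## candidate pools: genes that may be knocked out / knocked in
gdict_candidate_pools <- function(gdict) {
  ko <- ki <- character()
  for (rows in gdict$rows) {
    for (row in rows) {
      ko <- c(ko, row$K)
      ki <- c(ki, row$N)
    }
  }
  list(ko = csort(unique(ko)), ki = csort(unique(ki)))
}

#' Render a GDict as binary G/F constraint matrices
#'
#' One row per intervention row, ordered by (reaction order in the GDict,
#' canonical row order); `G[i, g] = 1` iff gene `g` is in the knockout set
#' of row `i`, `F[i, g] = 1` iff in the knock-in set.
#'
#' @param gdict A `gdict`.
#' @param gene_order Ordered gene universe (must cover all GDict genes;
#'   default [gdict_genes()]).
#' @return List with binary matrices `G`, `F` (rows x genes) and
#'   `row_reactions` (reaction id per row).
#' @export
gdict_to_matrices <- function(gdict, gene_order = gdict_genes(gdict)) {
  miss <- setdiff(gdict_genes(gdict), gene_order)
  if (length(miss)) stop2("gene_order lacks GDict gene(s): ", paste(miss, collapse = ", "))
  n_rows <- sum(lengths(gdict$rows))
  G <- F_ <- matrix(0L, n_rows, length(gene_order),
                    dimnames = list(NULL, gene_order))
  row_reactions <- character(n_rows)
  i <- 0L
  for (r in names(gdict$rows)) {
    for (row in gdict$rows[[r]]) {
      i <- i + 1L
      G[i, row$K] <- 1L
      F_[i, row$N] <- 1L
      row_reactions[i] <- r
    }
  }
  list(G = G, F = F_, row_reactions = row_reactions)
}

#' Export G/F matrices as CSV plus a row-index TSV
#' @param mats Result of [gdict_to_matrices()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_gf_matrices <- function(mats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(mats$G, file.path(dir, "G.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(mats$F, file.path(dir, "F.csv"), row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(row = seq_along(mats$row_reactions),
                                reaction = mats$row_reactions),
                     file.path(dir, "rows.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
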