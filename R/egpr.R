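## Extended GPR construction: per reaction, expand the GPR Boolean rule
## layer by layer with the signed regulatory network, allowing cycles, and
## verify after each per-gene expansion that the reaction marker remains
## attainable in some attractor (minimal trap space); otherwise the
## expansion is reverted and the gene stays a free input.

#' Combine signed regulators into an update rule
#'
#' The default threshold-free convention: a gene is on when at least one
#' activator is on and no repressor is on, i.e. `OR(activators) AND NOT
#' OR(repressors)`; with no activators the rule is `NOT OR(repressors)`,
#' with no repressors `OR(activators)`.
#'
#' @param activators,repressors Character vectors of regulator gene ids.
#' @return A `bool_expr`.
#' @export
combine_regulators <- function(activators, repressors) {
  activators <- csort(unique(as.character(activators)))
  repressors <- csort(unique(as.character(repressors)))
  if (!length(activators) && !length(repressors)) {
    stop2("combine_regulators() needs at least one regulator")
  }
  act <- if (length(activators)) bx_or(lapply(activators, bx_lit)) else NULL
  rep_ <- if (length(repressors)) bx_not(bx_or(lapply(repressors, bx_lit))) else NULL
  if (is.null(rep_)) act else if (is.null(act)) rep_ else bx_and(act, rep_)
}

#' Is the reaction marker attainable in some attractor?
#'
#' Under the default `"permissive"` sense, TRUE iff some minimal trap space
#' of the (unperturbed) network leaves the marker not fixed to 0, i.e. fixed
#' to 1 or unfixed.  Under `"strict"`, the marker must be fixed to 1 in some
#' minimal trap space.
#'
#' @param bn A `boolean_network` (or `egpr_network`).
#' @param marker Marker node id.
#' @param sense `"permissive"` or `"strict"`.
#' @return Logical.
#' @export
check_target_reachable <- function(bn, marker, sense = c("permissive", "strict")) {
  sense <- match.arg(sense)
  if (!marker %in% bn$nodes) stop2("marker node '", marker, "' not in network")
  ts <- minimal_trap_spaces(bn)
  for (s in ts) {
    v <- s[[marker]]
    if (sense == "permissive") {
      if (is.na(v) || v == 1L) return(TRUE)
    } else {
      if (!is.na(v) && v == 1L) return(TRUE)
    }
  }
  FALSE
}

#' Build the extended GPR Boolean network of a reaction
#'
#' Starting from the reaction's GPR (layer 0: the marker node's function
#' over its metabolic genes, all free inputs), each layer assigns to every
#' still-free gene with known regulators the combined regulatory rule
#' ([combine_regulators()]), adding missing regulators as new input nodes.
#' A regulator added within a layer whose own regulators are all already
#' present is wired back immediately, so feedback cycles (including
#' self-loops) are retained.  After each per-gene expansion the marker must
#' remain attainable ([check_target_reachable()]); otherwise that gene's
#' expansion is reverted (the gene stays a free input) and the event logged.
#' Genes within a layer are processed in lexicographic order, so the result
#' is deterministic.
#'
#' @param model A `metabolic_model`.
#' @param regnet A `regulatory_network`.
#' @param reaction Reaction id with a non-constant GPR.
#' @param layers Number of regulatory layers to expand (integer >= 0).
#' @param sense Reachability sense, see [check_target_reachable()].
#' @return An `egpr_network`: a `boolean_network` with fields `marker`
#'   (the reaction node), `layer` (named integer tags, 0 = GPR gene), and
#'   `log` (data frame of expansion events: gene, layer, action).
#' @export
expand_reaction <- function(model, regnet, reaction, layers = 1L,
                            sense = c("permissive", "strict")) {
  sense <- match.arg(sense)
  if (!reaction %in% model$reactions) stop2("reaction '", reaction, "' not in model")
  gpr <- model$gpr[[reaction]]
  if (is.null(gpr) || is_const_expr(gpr)) {
    stop2("reaction '", reaction, "' has no gene association to expand")
  }
  if (layers < 0L) stop2("layers must be >= 0")
  genes0 <- expr_vars(gpr)
  if (reaction %in% genes0) stop2("reaction id '", reaction, "' collides with a gene id")

  by_target <- split(seq_len(nrow(regnet)), regnet$target)
  regulators_of <- function(g) {
    idx <- by_target[[g]]
    if (is.null(idx)) return(NULL)
    list(act = csort(unique(regnet$source[idx][regnet$sign[idx] > 0])),
         rep = csort(unique(regnet$source[idx][regnet$sign[idx] < 0])))
  }

  f <- c(stats::setNames(list(gpr), reaction),
         stats::setNames(lapply(genes0, bx_lit), genes0))
  layer_tag <- stats::setNames(rep(0L, length(genes0) + 1L), c(reaction, genes0))
  log <- data.frame(gene = character(), layer = integer(), action = character(),
                    stringsAsFactors = FALSE)
  is_free <- function(fl, g) fl[[g]]$op == "lit" && fl[[g]]$var == g

  frontier <- genes0
  for (k in seq_len(layers)) {
    if (!length(frontier)) break
    added_this_layer <- character()
    for (g in csort(frontier)) {
      if (!is_free(f, g)) next                       # wired back earlier
      regs <- regulators_of(g)
      if (is.null(regs)) next                        # no known regulators: stays an input
      new_nodes <- setdiff(setdiff(union(regs$act, regs$rep), names(f)), reaction)
      f2 <- f
      for (u in new_nodes) f2[[u]] <- bx_lit(u)
      f2[[g]] <- combine_regulators(regs$act, regs$rep)
      ## wire back any newly added regulator whose regulators are all present
      for (u in csort(new_nodes)) {
        regs_u <- regulators_of(u)
        if (!is.null(regs_u) &&
            all(union(regs_u$act, regs_u$rep) %in% names(f2))) {
          f2[[u]] <- combine_regulators(regs_u$act, regs_u$rep)
        }
      }
      if (check_target_reachable(boolean_network(f2), reaction, sense)) {
        f <- f2
        layer_tag[new_nodes] <- k
        added_this_layer <- c(added_this_layer, new_nodes)
        log <- rbind(log, data.frame(gene = g, layer = k, action = "kept",
                                     stringsAsFactors = FALSE))
      } else {
        log <- rbind(log, data.frame(gene = g, layer = k, action = "reverted",
                                     stringsAsFactors = FALSE))
      }
    }
    frontier <- added_this_layer
  }

  bn <- boolean_network(f)
  bn$marker <- reaction
  bn$layer <- layer_tag[bn$nodes]
  bn$log <- log
  class(bn) <- c("egpr_network", class(bn))
  bn
}

#' @export
print.egpr_network <- function(x, ...) {
  cat("<egpr_network> marker ", x$marker, ", ", length(x$nodes), " nodes, ",
      max(x$layer), " layer(s)\n", sep = "")
  for (v in x$nodes) cat("  [", x$layer[[v]], "] ", v, " <- ", render_gpr(x$f[[v]]), "\n", sep = "")
  invisible(x)
}

#' Write per-reaction expansion logs as TSV
#' @param gdict A `gdict` built by [build_gdict()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expansion_log <- function(gdict, path) {
  logs <- attr(gdict, "expansion_log")
  if (is.null(logs)) logs <- data.frame(reaction = character(), gene = character(),
                                        layer = integer(), action = character())
  utils::write.table(logs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
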