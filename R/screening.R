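## Post-processing of gMISs against expression and CRISPR dependency
## screens: the attractor-based adaptation check, per-sample essential-gene
## prediction, screen labelling at the published thresholds, and Matthews
## correlation coefficient scoring.

#' Screening configuration
#'
#' @param expr_high_threshold A gene counts as highly expressed in a sample
#'   when its expression exceeds this value (same units as the matrix;
#'   default 1.0).
#' @param depmap_essential_cutoff DepMap genes are essential when the score
#'   is at or below this cutoff (default -0.6; boundary essential).
#' @param project_score_essential_cutoff Project Score genes are essential
#'   when the score is strictly above this cutoff (default 0; boundary
#'   non-essential).
#' @return A `screening_config`.
#' @export
screening_config <- function(expr_high_threshold = 1.0,
                             depmap_essential_cutoff = -0.6,
                             project_score_essential_cutoff = 0) {
  vals <- c(expr_high_threshold, depmap_essential_cutoff, project_score_essential_cutoff)
  if (any(!is.finite(vals))) stop2("screening cutoffs must be finite")
  structure(list(expr_high_threshold = expr_high_threshold,
                 depmap_essential_cutoff = depmap_essential_cutoff,
                 project_score_essential_cutoff = project_score_essential_cutoff),
            class = "screening_config")
}

#' Predict per-sample essential genes from gMISs and expression
#'
#' A knockout gene `g` of a gMIS is predicted essential in a sample when it
#' is the unique highly expressed gene among that gMIS's knockout members
#' (every other knockout member not highly expressed) and every knock-in
#' member is highly expressed: the intervention then collapses to the single
#' knockdown of `g` in that cellular context.
#'
#' @param gmis_list List of `gmis` (or `intervention_set`) objects.
#' @param expr An `expression_matrix` (genes x samples) covering every gMIS
#'   gene.
#' @param cfg A `screening_config`.
#' @return Named list (one entry per sample) of data frames with columns
#'   `gene` and `gmis` (index of the producing gMIS).
#' @export
predict_essential <- function(gmis_list, expr, cfg = screening_config()) {
  ivs <- lapply(gmis_list, function(g) if (inherits(g, "gmis")) g$interventions else g)
  all_genes <- csort(unique(unlist(lapply(ivs, function(iv) c(iv$KO, iv$KI)), use.names = FALSE)))
  miss <- setdiff(all_genes, rownames(expr))
  if (length(miss)) stop2("gMIS gene(s) missing from expression matrix: ",
                          paste(miss, collapse = ", "))
  samples <- colnames(expr)
  high <- unclass(expr) > cfg$expr_high_threshold
  out <- stats::setNames(vector("list", length(samples)), samples)
  for (s in samples) {
    genes <- character()
    src <- integer()
    for (i in seq_along(ivs)) {
      iv <- ivs[[i]]
      if (!length(iv$KO)) next
      ko_high <- iv$KO[high[iv$KO, s]]
      if (length(ko_high) != 1L) next
      if (length(iv$KI) && !all(high[iv$KI, s])) next
      genes <- c(genes, ko_high)
      src <- c(src, i)
    }
    keep <- !duplicated(genes)
    out[[s]] <- data.frame(gene = genes[keep], gmis = src[keep], stringsAsFactors = FALSE)
  }
  out
}

#' Attractor-based adaptation check of a gMIS
#'
#' For each single knockout member applied alone, the perturbed network must
#' admit at least one minimal trap space in which no other knockout member
#' of the gMIS is fixed to 1 and no knock-in member is fixed to 0.  When
#' some single knockout forces a partner gene into the opposite state in
#' every attractor, the network has adapted around the intervention: the
#' gMIS fails the check and its essential-gene calls should be discarded.
#'
#' @param bn A `boolean_network` containing all gMIS genes.
#' @param gmis A `gmis` or `intervention_set`.
#' @return TRUE (pass) or FALSE (flagged).
#' @export
adaptation_check <- function(bn, gmis) {
  iv <- if (inherits(gmis, "gmis")) gmis$interventions else gmis
  miss <- setdiff(c(iv$KO, iv$KI), bn$nodes)
  if (length(miss)) stop2("gMIS gene(s) not in network: ", paste(miss, collapse = ", "))
  for (g in iv$KO) {
    others_ko <- setdiff(iv$KO, g)
    ts <- minimal_trap_spaces(apply_perturbation(bn, intervention_set(KO = g)))
    ok <- any(vapply(ts, function(s) {
      ko_ok <- !length(others_ko) ||
        all(vapply(others_ko, function(u) is.na(s[[u]]) || s[[u]] != 1L, logical(1)))
      ki_ok <- !length(iv$KI) ||
        all(vapply(iv$KI, function(u) is.na(s[[u]]) || s[[u]] != 0L, logical(1)))
      ko_ok && ki_ok
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Label a dependency screen as essential / non-essential
#'
#' DepMap: essential iff score <= the DepMap cutoff (default -0.6, boundary
#' included).  Project Score: essential iff score > the Project Score
#' cutoff (default 0, boundary excluded).  Missing scores stay `NA` and are
#' excluded from evaluation.
#'
#' @param scores A `dependency_scores` matrix (genes x samples) with a
#'   `platform` attribute.
#' @param cfg A `screening_config`.
#' @return Integer matrix (1 essential, 0 not, NA missing), genes x samples.
#' @export
label_dependencies <- function(scores, cfg = screening_config()) {
  platform <- attr(scores, "platform")
  if (is.null(platform)) stop2("dependency scores lack a platform attribute")
  m <- unclass(scores)
  lab <- switch(platform,
    depmap = m <= cfg$depmap_essential_cutoff,
    project_score = m > cfg$project_score_essential_cutoff,
    stop2("unknown platform '", platform, "'")
  )
  mode(lab) <- "integer"
  lab
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' standard convention that the result is 0 when any factor of the
#' denominator is 0.
#'
#' @param c A list or vector with elements `TP`, `FP`, `TN`, `FN`.
#' @return A value in `[-1, 1]`.
#' @export
compute_mcc <- function(c) {
  tp <- as.numeric(c[["TP"]]); fp <- as.numeric(c[["FP"]])
  tn <- as.numeric(c[["TN"]]); fn <- as.numeric(c[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop2("confusion counts must be non-negative")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Evaluate essentiality predictions against screen labels
#'
#' Per sample, over the genes of `universe` that carry a (non-missing)
#' label: TP = predicted and essential, FP = predicted and not essential,
#' FN = essential but not predicted, TN = the rest.  Reports per-sample
#' confusion counts and MCC plus the pooled MCC over summed counts.
#'
#' @param pred Prediction map as returned by [predict_essential()] (a named
#'   list of data frames with a `gene` column, or of character vectors).
#' @param labels Label matrix as returned by [label_dependencies()].
#' @param universe Gene set over which predictions are defined (typically
#'   the knockout genes of the gMISs present in the screen); must be
#'   labelled genes.
#' @return An `evaluation_result`: data frame (sample, TP, FP, TN, FN, MCC)
#'   with the pooled MCC in `attr(, "pooled_mcc")`.
#' @export
evaluate_predictions <- function(pred, labels, universe) {
  universe <- csort(unique(as.character(universe)))
  if (!length(universe)) stop2("empty evaluation universe")
  miss <- setdiff(universe, rownames(labels))
  if (length(miss)) stop2("universe gene(s) unlabelled: ", paste(miss, collapse = ", "))
  samples <- intersect(names(pred), colnames(labels))
  rows <- lapply(samples, function(s) {
    p <- pred[[s]]
    p_genes <- if (is.data.frame(p)) p$gene else as.character(p)
    lab <- labels[universe, s]
    use <- !is.na(lab)
    g <- universe[use]
    ess <- lab[use] == 1L
    prd <- g %in% p_genes
    data.frame(sample = s,
               TP = sum(prd & ess), FP = sum(prd & !ess),
               TN = sum(!prd & !ess), FN = sum(!prd & ess),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$MCC <- vapply(seq_len(nrow(df)), function(i) compute_mcc(df[i, ]), numeric(1))
  pooled <- compute_mcc(list(TP = sum(df$TP), FP = sum(df$FP),
                             TN = sum(df$TN), FN = sum(df$FN)))
  structure(df, pooled_mcc = pooled, class = c("evaluation_result", "data.frame"))
}

#' @export
print.evaluation_result <- function(x, ...) {
  print.data.frame(x, ...)
  cat("pooled MCC:", attr(x, "pooled_mcc"), "\n")
  invisible(x)
}

#' Write per-sample evaluation as TSV
#' @param eval_result An `evaluation_result`.
#' @param path Output path.
#' @export
write_evaluation_tsv <- function(eval_result, path) {
  utils::write.table(as.data.frame(eval_result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write predictions as TSV (sample, gene, gMIS id)
#' @param pred Result of [predict_essential()].
#' @param path Output path.
#' @export
write_predictions_tsv <- function(pred, path) {
  rows <- lapply(names(pred), function(s) {
    p <- pred[[s]]
    if (!nrow(p)) return(NULL)
    data.frame(sample = s, gene = p$gene, gmis = p$gmis, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(list(data.frame(sample = character(), gene = character(),
                                         gmis = integer(), stringsAsFactors = FALSE)), rows))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
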