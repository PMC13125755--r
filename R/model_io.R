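## Reading and writing of external formats: metabolic models (JSON dialect
## and a minimal SBML L3V1 + fbc subset), signed regulatory networks (TSV),
## expression / dependency-score matrices (CSV), GDict (JSON) and Boolean
## networks (.bnet).

#' Construct a metabolic model
#'
#' A constraint-based metabolic model: stoichiometry, flux bounds, per-
#' reaction GPR rules, and the target reaction whose blocking defines
#' lethality.
#'
#' @param reactions Ordered character vector of reaction ids.
#' @param metabolites Ordered character vector of metabolite ids.
#' @param S Stoichiometric matrix, `length(metabolites)` x
#'   `length(reactions)`.
#' @param lb,ub Per-reaction flux bounds (named or in reaction order).
#' @param gpr Named list of `bool_expr` (or GPR strings) keyed by reaction
#'   id; reactions absent from the list are unconstrained (constant-1 GPR).
#' @param target Reaction id whose blocking defines the lethal phenotype.
#' @param id Model identifier string.
#' @return A `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, S, lb, ub, gpr = list(),
                            target, id = "model") {
  reactions <- as.character(reactions)
  metabolites <- as.character(metabolites)
  S <- as.matrix(S)
  if (!all(dim(S) == c(length(metabolites), length(reactions)))) {
    stop2("S must be ", length(metabolites), " x ", length(reactions),
          ", got ", nrow(S), " x ", ncol(S))
  }
  dimnames(S) <- list(metabolites, reactions)
  lb <- stats::setNames(as.numeric(lb), reactions)
  ub <- stats::setNames(as.numeric(ub), reactions)
  if (any(lb > ub)) {
    bad <- reactions[lb > ub]
    stop2("lb > ub for reaction(s): ", paste(bad, collapse = ", "))
  }
  if (!target %in% reactions) stop2("target reaction '", target, "' not in model")
  gpr <- lapply(gpr, function(g) if (is.character(g)) parse_gpr(g) else g)
  bad <- setdiff(names(gpr), reactions)
  if (length(bad)) stop2("GPR for unknown reaction(s): ", paste(bad, collapse = ", "))
  for (r in names(gpr)) {
    if (!inherits(gpr[[r]], "bool_expr")) stop2("GPR of '", r, "' is not a bool_expr")
    if (any(!nzchar(expr_vars(gpr[[r]])))) stop2("empty gene token in GPR of '", r, "'")
  }
  structure(list(id = id, reactions = reactions, metabolites = metabolites,
                 S = S, lb = lb, ub = ub, gpr = gpr, target = target),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> '", x$id, "': ", length(x$reactions), " reactions, ",
      length(x$metabolites), " metabolites, target ", x$target, "\n", sep = "")
  invisible(x)
}

#' Genes of a metabolic model
#' @param model A `metabolic_model`.
#' @return Sorted character vector of all genes appearing in any GPR.
#' @export
model_genes <- function(model) {
  csort(unique(unlist(lapply(model$gpr, expr_vars), use.names = FALSE)))
}

## ---- JSON model dialect -----------------------------------------------

#' Write a metabolic model as canonical JSON
#'
#' The dialect is a single object with sorted keys: `id`, `target`,
#' `metabolites` (array), and `reactions` (array of `{gpr, id, lb,
#' metabolites, ub}` objects, `gpr` omitted when unconstrained).  Canonical
#' serialization makes artifacts diffable: write / load / write is
#' byte-identical.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(model$reactions, function(r) {
    coef <- model$S[, r]
    coef <- coef[coef != 0]
    obj <- list(id = r, lb = model$lb[[r]], ub = model$ub[[r]],
                metabolites = as.list(coef[corder(names(coef))]))
    if (!is.null(model$gpr[[r]])) obj$gpr <- render_gpr(model$gpr[[r]])
    obj[corder(names(obj))]
  })
  top <- list(id = model$id, metabolites = as.list(model$metabolites),
              reactions = rxns, target = model$target)
  jsonlite::write_json(top[corder(names(top))], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

load_model_json <- function(path) {
  top <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop2("cannot parse JSON model '", path, "': ",
                                            conditionMessage(e)))
  for (key in c("id", "metabolites", "reactions", "target")) {
    if (is.null(top[[key]])) stop2("JSON model '", path, "' lacks element '", key, "'")
  }
  mets <- unlist(top$metabolites)
  rids <- vapply(top$reactions, function(r) r$id %||% stop2("reaction without id in '", path, "'"), "")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids))
  gpr <- list()
  for (i in seq_along(top$reactions)) {
    r <- top$reactions[[i]]
    lb[i] <- r$lb %||% stop2("reaction '", r$id, "' lacks lb")
    ub[i] <- r$ub %||% stop2("reaction '", r$id, "' lacks ub")
    for (m in names(r$metabolites)) {
      if (!m %in% mets) stop2("reaction '", r$id, "' references unknown metabolite '", m, "'")
      S[m, i] <- as.numeric(r$metabolites[[m]])
    }
    if (!is.null(r$gpr)) gpr[[r$id]] <- parse_gpr(r$gpr)
  }
  metabolic_model(rids, mets, S, lb, ub, gpr, target = top$target, id = top$id)
}

## ---- minimal SBML L3V1 + fbc subset -----------------------------------

## Supported subset: one compartment, species, reactions with reactant /
## product stoichiometries, flux bounds via fbc bound parameters, GPRs as
## fbc geneProductAssociation (and/or only; fbc cannot express NOT), and the
## target reaction id carried in a model annotation.

sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
anno_ns <- "https://example.org/gmisnet"

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  gpa <- function(e) {
    switch(e$op,
      lit = paste0('<fbc:geneProductRef fbc:geneProduct="', esc(e$var), '"/>'),
      and = paste0("<fbc:and>", paste(vapply(e$args, gpa, ""), collapse = ""), "</fbc:and>"),
      or = paste0("<fbc:or>", paste(vapply(e$args, gpa, ""), collapse = ""), "</fbc:or>"),
      stop2("GPR operator '", e$op, "' cannot be expressed in SBML fbc")
    )
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            sbml_ns, fbc_ns),
    sprintf('<model id="%s" fbc:strict="true">', esc(model$id)),
    sprintf('<annotation><gn:target xmlns:gn="%s">%s</gn:target></annotation>',
            anno_ns, esc(model$target)),
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "<listOfSpecies>",
    sprintf('<species id="%s" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
            vapply(model$metabolites, esc, "")),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="bnd_lb_%s" value="%.17g" constant="true"/>',
            vapply(model$reactions, esc, ""), model$lb),
    sprintf('<parameter id="bnd_ub_%s" value="%.17g" constant="true"/>',
            vapply(model$reactions, esc, ""), model$ub),
    "</listOfParameters>",
    "<fbc:listOfGeneProducts>",
    if (length(model_genes(model))) {
      sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
              vapply(model_genes(model), esc, ""), vapply(model_genes(model), esc, ""))
    } else character(0),
    "</fbc:listOfGeneProducts>",
    "<listOfReactions>"
  )
  for (r in model$reactions) {
    coef <- model$S[, r]
    reac <- names(coef)[coef < 0]
    prod <- names(coef)[coef > 0]
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="bnd_lb_%s" fbc:upperFluxBound="bnd_ub_%s">',
      esc(r), tolower(model$lb[[r]] < 0), esc(r), esc(r)))
    if (length(reac)) {
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         vapply(reac, esc, ""), -coef[reac]),
                 "</listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         vapply(prod, esc, ""), coef[prod]),
                 "</listOfProducts>")
    }
    if (!is.null(model$gpr[[r]])) {
      lines <- c(lines, paste0("<fbc:geneProductAssociation>", gpa(model$gpr[[r]]),
                               "</fbc:geneProductAssociation>"))
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

load_model_sbml <- function(path, target = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop2("cannot parse SBML '", path, "': ",
                                            conditionMessage(e)))
  loc <- function(node, name) xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  model_node <- loc(doc, "model")
  if (length(model_node) == 0L) stop2("SBML '", path, "' has no <model> element")
  model_node <- model_node[[1L]]
  id <- xml2::xml_attr(model_node, "id") %||% "model"
  mets <- xml2::xml_attr(loc(model_node, "species"), "id")
  params <- loc(model_node, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  rxn_nodes <- loc(model_node, "reaction")
  rids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids))
  gpr <- list()
  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      g <- xml2::xml_attr(node, "geneProduct")
      if (is.na(g) || !nzchar(g)) stop2("geneProductRef without fbc:geneProduct in '", path, "'")
      return(bx_lit(g))
    }
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parse_gpa)
    if (nm == "and") bx_and(args) else if (nm == "or") bx_or(args)
    else stop2("unsupported gene-association element <", nm, "> in '", path, "'")
  }
  for (i in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[i]]
    lbid <- xml2::xml_attr(rn, "lowerFluxBound")
    ubid <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(lbid) || is.na(ubid) || !lbid %in% names(pvals) || !ubid %in% names(pvals)) {
      stop2("reaction '", rids[i], "' lacks resolvable flux-bound parameters in '", path, "'")
    }
    lb[i] <- pvals[[lbid]]
    ub[i] <- pvals[[ubid]]
    for (sr in loc(rn, "speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      parent <- xml2::xml_name(xml2::xml_parent(sr))
      S[sp, i] <- S[sp, i] + if (parent == "listOfReactants") -st else st
    }
    gpa <- loc(rn, "geneProductAssociation")
    if (length(gpa)) {
      kids <- xml2::xml_children(gpa[[1L]])
      if (length(kids) != 1L) stop2("malformed geneProductAssociation for '", rids[i], "'")
      gpr[[rids[i]]] <- parse_gpa(kids[[1L]])
    }
  }
  anno <- loc(model_node, "target")
  if (is.null(target)) {
    if (length(anno)) target <- xml2::xml_text(anno[[1L]])
    else stop2("SBML '", path, "' carries no target annotation; pass `target=`")
  }
  metabolic_model(rids, mets, S, lb, ub, gpr, target = target, id = id)
}

#' Load a metabolic model
#'
#' @param path File path.
#' @param format `"json"` (the package's canonical dialect, see
#'   [write_model_json()]) or `"sbml"` (minimal SBML L3V1 + fbc subset).
#' @param target Target reaction id override (required for SBML files that
#'   carry no target annotation).
#' @return A `metabolic_model`; reactions without a GPR are unconstrained.
#' @export
load_metabolic_model <- function(path, format = c("json", "sbml"), target = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("model file '", path, "' does not exist")
  m <- switch(format, json = load_model_json(path), sbml = load_model_sbml(path, target))
  if (!is.null(target) && format == "json") {
    m <- metabolic_model(m$reactions, m$metabolites, m$S, m$lb, m$ub, m$gpr,
                         target = target, id = m$id)
  }
  m
}

## ---- regulatory networks ----------------------------------------------

#' Construct a signed regulatory network
#'
#' @param source,target Character vectors of gene ids.
#' @param sign Integer vector over `{+1, -1}` (+1 activation, -1
#'   repression).
#' @return A `regulatory_network` data frame with duplicate edges collapsed.
#' @export
regulatory_network <- function(source = character(), target = character(),
                               sign = integer()) {
  sign <- as.integer(sign)
  if (any(!sign %in% c(-1L, 1L))) stop2("edge signs must be +1 or -1")
  df <- data.frame(source = as.character(source), target = as.character(target),
                   sign = sign, stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[corder(df$source, df$target, df$sign), , drop = FALSE]
  rownames(df) <- NULL
  conflict <- unique(df[duplicated(df[c("source", "target")]), c("source", "target")])
  if (nrow(conflict)) {
    warning("conflicting-sign edge pair(s) retained: ",
            paste(paste0(conflict$source, "->", conflict$target), collapse = ", "),
            call. = FALSE)
  }
  class(df) <- c("regulatory_network", "data.frame")
  df
}

REGNET_SIGNS <- c("+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L, "1" = 1L,
                  "−1" = -1L, "−" = -1L,
                  "activation" = 1L, "repression" = -1L)

#' Load a regulatory network from a 3-column TSV
#'
#' Columns are source, target, sign (header row optional).  Sign tokens
#' `+`, `-`, `+1`, `-1`, `1`, `−1`, `activation`, `repression` are
#' normalized to +1/-1.  Duplicate rows are collapsed; a pair with both
#' signs is kept as two edges with a warning.
#'
#' @param path TSV file path.
#' @return A `regulatory_network`.
#' @export
load_regulatory_network <- function(path) {
  if (!file.exists(path)) stop2("regulatory network file '", path, "' does not exist")
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(raw) != 3L) stop2("'", path, "' must have 3 columns (source, target, sign), got ", ncol(raw))
  names(raw) <- c("source", "target", "sign")
  if (nrow(raw) && tolower(raw$sign[1]) == "sign") raw <- raw[-1L, , drop = FALSE]
  if (!nrow(raw)) return(regulatory_network())
  tok <- tolower(trimws(raw$sign))
  unknown <- which(!tok %in% names(REGNET_SIGNS))
  if (length(unknown)) {
    stop2("unknown sign token '", raw$sign[unknown[1L]], "' at row ", unknown[1L],
          " of '", path, "'")
  }
  regulatory_network(trimws(raw$source), trimws(raw$target), REGNET_SIGNS[tok])
}

#' Write a regulatory network as TSV
#' @param regnet A `regulatory_network`.
#' @param path Output path.
#' @export
write_regulatory_network <- function(regnet, path) {
  df <- as.data.frame(regnet)
  df$sign <- ifelse(df$sign > 0, "+1", "-1")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- expression / dependency matrices ---------------------------------

#' Load a genes-by-samples matrix from CSV
#'
#' First column holds gene ids, header row holds sample ids.
#'
#' @param path CSV file path.
#' @param kind `"expression"` (all values must be finite) or `"scores"`
#'   (dependency screen; missing values allowed and excluded from
#'   evaluation).
#' @param platform For `kind = "scores"`: `"depmap"` or `"project_score"`.
#' @return A numeric matrix of class `expression_matrix` or
#'   `dependency_scores` (the latter with a `platform` attribute).
#' @export
load_matrix <- function(path, kind = c("expression", "scores"), platform = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop2("matrix file '", path, "' does not exist")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop2("'", path, "' has no sample columns")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop2("duplicated gene id(s) in '", path, "': ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (any(!nzchar(genes)) || anyNA(genes)) stop2("missing gene id in '", path, "'")
  vals <- df[-1L]
  m <- matrix(NA_real_, nrow(df), ncol(vals), dimnames = list(genes, names(vals)))
  for (j in seq_along(vals)) {
    x <- trimws(vals[[j]])
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & nzchar(x) & !toupper(x) %in% c("NA", "NAN"))
    if (length(bad)) {
      stop2("non-numeric value '", x[bad[1L]], "' at row ", bad[1L], " (gene ",
            genes[bad[1L]], "), column '", names(vals)[j], "' of '", path, "'")
    }
    m[, j] <- num
  }
  if (kind == "expression") {
    if (any(!is.finite(m))) stop2("expression matrix '", path, "' contains non-finite values")
    structure(m, class = c("expression_matrix", class(m)))
  } else {
    if (is.null(platform)) stop2("dependency scores need a platform ('depmap' or 'project_score')")
    platform <- match.arg(platform, c("depmap", "project_score"))
    if (any(is.infinite(m))) stop2("dependency scores '", path, "' contain infinite values")
    structure(m, class = c("dependency_scores", class(m)), platform = platform)
  }
}

#' Write a genes-by-samples matrix as CSV
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- GDict serialization ----------------------------------------------

#' Serialize / deserialize a GDict as JSON
#'
#' Format: an object mapping each reaction id to an array of
#' `{"K": [genes], "N": [genes]}` rows, plus a reserved `"_provenance"`
#' entry (layers, kmax, model id).  Keys are sorted so artifacts are
#' diffable; write / read round-trips to a structurally identical GDict.
#'
#' @param gdict A `gdict`.
#' @param path File path.
#' @export
write_gdict <- function(gdict, path) {
  obj <- lapply(gdict$rows, function(rows) {
    lapply(rows, function(row) list(K = as.list(row$K), N = as.list(row$N)))
  })
  if (length(obj)) obj <- obj[corder(names(obj))]
  if (length(gdict$provenance)) {
    obj[["_provenance"]] <- gdict$provenance[corder(names(gdict$provenance))]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gdict
#' @param reaction_order Optional reaction ordering to restore (defaults to
#'   the file's sorted order).
#' @return `read_gdict()` returns a `gdict`.
#' @export
read_gdict <- function(path, reaction_order = NULL) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop2("cannot parse GDict '", path, "': ",
                                            conditionMessage(e)))
  prov <- obj[["_provenance"]] %||% list()
  obj[["_provenance"]] <- NULL
  rows <- lapply(obj, function(rlist) {
    lapply(rlist, function(row) {
      K <- csort(unlist(row$K) %||% character(0))
      N <- csort(unlist(row$N) %||% character(0))
      if (length(intersect(K, N))) {
        stop2("invalid GDict row in '", path, "': gene(s) ",
              paste(intersect(K, N), collapse = ", "), " in both K and N")
      }
      if (!length(K) && !length(N)) stop2("invalid empty GDict row in '", path, "'")
      list(K = as.character(K), N = as.character(N))
    })
  })
  if (!is.null(reaction_order)) {
    miss <- setdiff(names(rows), reaction_order)
    if (length(miss)) stop2("GDict reactions not in requested order: ", paste(miss, collapse = ", "))
    rows <- rows[intersect(reaction_order, names(rows))]
  }
  new_gdict(rows, provenance = prov)
}
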