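## Boolean-network dynamics: minimal trap spaces, perturbations, and
## enumeration of minimal marker-inactivating intervention sets.
##
## Semantics: attractors are identified with minimal trap spaces (subcubes
## closed under the update functions with no strictly contained trap space).
## This makes results independent of the update scheme and brute-forceable.
## Free inputs are encoded as self-referential functions f(v) = v so that a
## trap space may leave them unfixed.

#' Construct a Boolean network
#'
#' @param f Named list of `bool_expr` update functions, one per node.  A node
#'   whose function is its own literal (`f[[v]] = bx_lit(v)`) is a free input.
#'   Every variable read by any function must itself be a node.
#' @return A `boolean_network` with nodes in canonical (sorted) order.
#' @export
#' @examples
#' bn <- boolean_network(list(r1 = bx_not(bx_lit("r2")), r2 = bx_not(bx_lit("r1"))))
#' minimal_trap_spaces(bn)
boolean_network <- function(f) {
  if (!is.list(f) || is.null(names(f)) || any(!nzchar(names(f)))) {
    stop2("f must be a named list of update functions")
  }
  if (anyDuplicated(names(f))) stop2("duplicate node names: ",
    paste(unique(names(f)[duplicated(names(f))]), collapse = ", "))
  nodes <- csort(names(f))
  f <- f[nodes]
  for (v in nodes) {
    if (!inherits(f[[v]], "bool_expr")) stop2("update function of '", v, "' is not a bool_expr")
    miss <- setdiff(expr_vars(f[[v]]), nodes)
    if (length(miss)) {
      stop2("function of '", v, "' reads undeclared node(s): ", paste(miss, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, f = f), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("<boolean_network> ", length(x$nodes), " nodes\n", sep = "")
  for (v in x$nodes) cat("  ", v, " <- ", render_gpr(x$f[[v]]), "\n", sep = "")
  invisible(x)
}

bn_is_input <- function(bn, v) {
  e <- bn$f[[v]]
  e$op == "lit" && e$var == v
}

#' Free-input nodes of a network
#' @param bn A `boolean_network`.
#' @return Character vector of nodes whose function is their own literal.
#' @export
bn_inputs <- function(bn) {
  bn$nodes[vapply(bn$nodes, function(v) bn_is_input(bn, v), logical(1))]
}

#' Write a Boolean network in .bnet format
#'
#' One `node, function` line per node, with `&`, `|`, `!` operators, for
#' interoperability with external Boolean-network tools.
#'
#' @param bn A `boolean_network`.
#' @param path Output file path.
#' @export
write_bnet <- function(bn, path) {
  to_bnet <- function(e) {
    s <- render_gpr(e)
    s <- gsub("\\bnot\\b", "!", s)
    s <- gsub("\\band\\b", "&", s)
    s <- gsub("\\bor\\b", "|", s)
    gsub("! ", "!", s, fixed = TRUE)
  }
  lines <- c("targets, factors",
             vapply(bn$nodes, function(v) paste0(v, ", ", to_bnet(bn$f[[v]])), ""))
  writeLines(lines, path)
  invisible(path)
}

## ---- prime implicants -------------------------------------------------

## Prime implicants of [expr == val] over `vars`, as a list of named 0/1
## integer vectors (possibly the empty implicant when the function is
## constant).  Subcube enumeration: fine for the small arities of GPRs and
## regulatory update rules.
prime_implicants <- function(expr, val, vars = expr_vars(expr)) {
  if (length(vars) == 0L) {
    v <- eval_expr(expr, integer())
    return(if (v == val) list(structure(integer(0), names = character(0))) else list())
  }
  prime_implicants_tt(expr_tt(expr, vars)$tt, vars, val)
}

## Prime implicants from an explicit truth table (row index = 1 + binary
## encoding of vars in order, least significant first).
prime_implicants_tt <- function(tt, vars, val) {
  k <- length(vars)
  if (k > 12L) stop2("prime implicants over ", k, " variables not supported")
  hit <- tt == val
  ## enumerate subcubes in base 3 over vars: digit 0 -> var=0, 1 -> var=1, 2 -> free
  n_sub <- 3L^k
  digits <- matrix(0L, n_sub, k)
  rep_each <- 1L
  for (j in seq_len(k)) {
    digits[, j] <- rep(rep(0:2, each = rep_each), length.out = n_sub)
    rep_each <- rep_each * 3L
  }
  ## implicant test: all truth-table rows consistent with the subcube hit `val`
  pow2 <- bitwShiftL(1L, seq_len(k) - 1L)
  is_implicant <- logical(n_sub)
  for (i in seq_len(n_sub)) {
    d <- digits[i, ]
    free <- which(d == 2L)
    base <- 1L + sum(pow2[d == 1L])
    if (length(free) == 0L) {
      is_implicant[i] <- hit[base]
    } else {
      idx <- base
      for (fj in free) idx <- c(idx, idx + pow2[fj])
      is_implicant[i] <- all(hit[idx])
    }
  }
  ## prime: implicant and no single fixed literal can be freed
  out <- list()
  for (i in which(is_implicant)) {
    d <- digits[i, ]
    fixed <- which(d != 2L)
    prime <- TRUE
    for (fj in fixed) {
      d2 <- d
      d2[fj] <- 2L
      i2 <- 1L + sum(d2 * 3L^(seq_len(k) - 1L))
      if (is_implicant[i2]) { prime <- FALSE; break }
    }
    if (prime) {
      out[[length(out) + 1L]] <- structure(d[fixed], names = vars[fixed])
    }
  }
  out
}

## Per-node prime implicant tables: pi0[[v]], pi1[[v]]
bn_implicants <- function(bn) {
  pi0 <- pi1 <- vector("list", length(bn$nodes))
  names(pi0) <- names(pi1) <- bn$nodes
  for (v in bn$nodes) {
    e <- bn$f[[v]]
    pi1[[v]] <- prime_implicants(e, 1L)
    pi0[[v]] <- prime_implicants(e, 0L)
  }
  list(pi0 = pi0, pi1 = pi1)
}

## ---- minimal trap spaces ----------------------------------------------

## A subcube (partial assignment L of literals node -> 0/1, free elsewhere)
## is a trap space iff every fixed literal (v, c) is *supported*: some prime
## implicant of [f_v == c] has all its literals in L.  Minimal trap spaces
## are exactly the maximal consistent supported literal sets.  We enumerate
## them by a branch search over node states {0, 1, free}, resolving support
## obligations by branching over prime implicants, then keep the literal-set
## maximal results.

#' Minimal trap spaces of a Boolean network
#'
#' Computes all inclusion-minimal trap spaces (subcubes closed under the
#' update functions), which serve as the network's attractors under
#' most-permissive-style semantics.  Free inputs may be fixed or left free by
#' a trap space.
#'
#' @param bn A `boolean_network`.
#' @return List of subcubes in canonical order.  Each subcube is a named
#'   integer vector over all nodes with values 0, 1, or `NA` (free).
#' @seealso [trap_spaces_exhaustive()] for the brute-force reference.
#' @export
minimal_trap_spaces <- function(bn) {
  nodes <- bn$nodes
  pis <- bn_implicants(bn)
  results <- new.env(parent = emptyenv())

  supported <- function(L, v, c) {
    plist <- if (c == 1L) pis$pi1[[v]] else pis$pi0[[v]]
    for (p in plist) {
      if (length(p) == 0L) return(TRUE)
      nm <- names(p)
      if (all(nm %in% names(L)) && all(L[nm] == p)) return(TRUE)
    }
    FALSE
  }

  ## Resolve pending support obligations; returns list of supported,
  ## consistent supersets of L (literals on banned nodes may not be added).
  resolve <- function(L, pending, banned) {
    while (length(pending)) {
      ob <- pending[[1L]]
      pending <- pending[-1L]
      v <- ob[[1L]]; c <- ob[[2L]]
      if (supported(L, v, c)) next
      plist <- if (c == 1L) pis$pi1[[v]] else pis$pi0[[v]]
      out <- list()
      for (p in plist) {
        nm <- names(p)
        known <- nm %in% names(L)
        if (any(known) && any(L[nm[known]] != p[known])) next   # inconsistent
        new_nm <- nm[!known]
        if (any(new_nm %in% banned)) next
        L2 <- c(L, p[!known])
        pend2 <- pending
        for (u in new_nm) pend2[[length(pend2) + 1L]] <- list(u, L2[[u]])
        out <- c(out, resolve(L2, pend2, banned))
      }
      return(out)
    }
    list(L)
  }

  recurse <- function(L, banned, und) {
    und <- und[!(und %in% names(L)) & !(und %in% banned)]
    if (!length(und)) {
      key <- paste0("k:", lit_key(L))
      if (is.null(results[[key]])) results[[key]] <- L
      return(invisible(NULL))
    }
    v <- und[[1L]]
    rest <- und[-1L]
    for (c in c(0L, 1L)) {
      L2 <- c(L, structure(c, names = v))
      for (L3 in resolve(L2, list(list(v, c)), banned)) recurse(L3, banned, rest)
    }
    ## A leaf where an input or constant node stays free is never maximal
    ## (it can always be extended), so skip the free branch for those.
    e <- bn$f[[v]]
    skip_free <- bn_is_input(bn, v) || e$op == "const"
    if (!skip_free) recurse(L, c(banned, v), rest)
    invisible(NULL)
  }

  recurse(structure(integer(0), names = character(0)), character(0), nodes)

  sets <- as.list(results)
  sets <- unname(sets[corder(names(sets))])
  ## keep literal-set maximal (== subcube minimal)
  if (length(sets) > 1L) {
    sizes <- vapply(sets, length, integer(1))
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      Li <- sets[[i]]
      for (j in seq_along(sets)) {
        if (i == j || sizes[j] <= sizes[i]) next
        Lj <- sets[[j]]
        nm <- names(Li)
        if (all(nm %in% names(Lj)) && all(Lj[nm] == Li)) { keep[i] <- FALSE; break }
      }
    }
    sets <- sets[keep]
  }
  out <- lapply(sets, function(L) {
    s <- rep(NA_integer_, length(nodes))
    names(s) <- nodes
    if (length(L)) s[names(L)] <- L
    s
  })
  out[corder(vapply(out, subcube_key, ""))]
}

subcube_key <- function(s) {
  paste(paste0(names(s), "=", ifelse(is.na(s), "*", s)), collapse = ",")
}

## ---- perturbations ----------------------------------------------------

#' Construct an intervention set
#'
#' A signed set of gene perturbations: knockouts (fixed to 0) and knock-ins
#' (fixed to 1).
#'
#' @param KO Character vector of knockout genes.
#' @param KI Character vector of knock-in genes.
#' @return An `intervention_set` with sorted, disjoint components.
#' @export
intervention_set <- function(KO = character(), KI = character()) {
  KO <- csort(unique(as.character(KO)))
  KI <- csort(unique(as.character(KI)))
  if (length(intersect(KO, KI))) {
    stop2("a gene cannot be both knocked out and knocked in: ",
          paste(intersect(KO, KI), collapse = ", "))
  }
  structure(list(KO = KO, KI = KI), class = "intervention_set")
}

#' @export
print.intervention_set <- function(x, ...) {
  cat("<intervention_set> ", iv_label(x), "\n", sep = "")
  invisible(x)
}

iv_label <- function(iv) {
  parts <- c(if (length(iv$KO)) paste0(iv$KO, "-"), if (length(iv$KI)) paste0(iv$KI, "+"))
  if (!length(parts)) "{}" else paste0("{", paste(parts, collapse = ";"), "}")
}

iv_size <- function(iv) length(iv$KO) + length(iv$KI)

## signed-literal subset relation: a <= b
iv_subset <- function(a, b) all(a$KO %in% b$KO) && all(a$KI %in% b$KI)

## canonical sort: by size, then lexicographic KO, then lexicographic KI
iv_sort_key <- function(iv) {
  sprintf("%03d|%s|%s", iv_size(iv), paste(iv$KO, collapse = ","), paste(iv$KI, collapse = ","))
}

sort_intervention_sets <- function(ivs) ivs[corder(vapply(ivs, iv_sort_key, ""))]

#' Apply a perturbation to a Boolean network
#'
#' Knockout nodes get the constant-0 update function, knock-in nodes the
#' constant-1 function; all other functions are untouched.
#'
#' @param bn A `boolean_network`.
#' @param p An `intervention_set` over nodes of `bn`.
#' @return The perturbed `boolean_network`.
#' @export
apply_perturbation <- function(bn, p) {
  if (!inherits(p, "intervention_set")) p <- intervention_set(p$KO %||% character(), p$KI %||% character())
  miss <- setdiff(c(p$KO, p$KI), bn$nodes)
  if (length(miss)) stop2("perturbed gene(s) not in network: ", paste(miss, collapse = ", "))
  f <- bn$f
  for (g in p$KO) f[[g]] <- bx_const(0L)
  for (g in p$KI) f[[g]] <- bx_const(1L)
  boolean_network(f)
}

## TRUE iff every minimal trap space of bn fixes `marker` to 0
marker_inactivated <- function(bn, marker) {
  ts <- minimal_trap_spaces(bn)
  for (s in ts) {
    v <- s[[marker]]
    if (is.na(v) || v != 0L) return(FALSE)
  }
  TRUE
}

#' Minimal marker-inactivating intervention sets
#'
#' Enumerates all inclusion-minimal intervention sets of size at most `kmax`
#' such that every minimal trap space of the perturbed network fixes `marker`
#' to 0 (the marker-reprogramming problem with an inactivation marker).  The
#' marker node itself is never a candidate.
#'
#' @param bn A `boolean_network`.
#' @param marker Node whose inactivation is required.
#' @param kmax Maximum intervention-set size (default 3).
#' @param candidates Candidate genes (default: all nodes but the marker).
#' @return List of `intervention_set` in canonical (size, lexicographic)
#'   order; an antichain under signed inclusion.
#' @seealso [inactivating_sets_exhaustive()] for the brute-force reference.
#' @export
minimal_inactivating_sets <- function(bn, marker, kmax = 3L,
                                      candidates = setdiff(bn$nodes, marker)) {
  if (!marker %in% bn$nodes) stop2("marker node '", marker, "' not in network")
  if (kmax < 1L) stop2("kmax must be >= 1")
  candidates <- csort(setdiff(candidates, marker))
  found <- list()
  for (size in seq_len(min(kmax, length(candidates)))) {
    combos <- utils::combn(candidates, size, simplify = FALSE)
    for (genes in combos) {
      ## every 0/1 sign pattern over the chosen genes
      for (mask in 0:(2L^size - 1L)) {
        ki_sel <- bitwAnd(bitwShiftR(mask, seq_len(size) - 1L), 1L) == 1L
        iv <- intervention_set(KO = genes[!ki_sel], KI = genes[ki_sel])
        if (any(vapply(found, iv_subset, logical(1), b = iv))) next
        if (marker_inactivated(apply_perturbation(bn, iv), marker)) {
          found[[length(found) + 1L]] <- iv
        }
      }
    }
  }
  sort_intervention_sets(found)
}
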