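## Dense two-phase primal simplex for the flux-balance feasibility LPs.
##
## Problem form: maximize c'x subject to A x = b, 0 <= x <= u (all data
## finite, u >= 0).  Bounds are carried as explicit slack rows x_i + s_i =
## u_i, so every variable is bounded and phase 2 cannot be unbounded.
## Bland's rule (smallest-index entering variable, smallest-index leaving
## tie-break) guarantees termination under degeneracy.  Problem sizes here
## are tiny (tens of reactions), so a dense tableau is appropriate.

lp_pivot <- function(tab, basis, pr, pc) {
  tab[pr, ] <- tab[pr, ] / tab[pr, pc]
  for (r in seq_len(nrow(tab))) {
    if (r != pr && tab[r, pc] != 0) tab[r, ] <- tab[r, ] - tab[r, pc] * tab[pr, ]
  }
  basis[pr] <- pc
  list(tab = tab, basis = basis)
}

## Maximize cost over columns `active`, tableau in canonical form w.r.t.
## basis.  Returns updated tableau/basis; status "optimal" or "iterlimit".
lp_iterate <- function(tab, basis, cost, active, tol = 1e-9, max_iter = 10000L) {
  rhs_col <- ncol(tab)
  for (it in seq_len(max_iter)) {
    red <- cost[active] - as.numeric(cost[basis] %*% tab[, active, drop = FALSE])
    ent <- active[which(red > tol)]
    if (!length(ent)) return(list(tab = tab, basis = basis, status = "optimal"))
    pc <- ent[1L]                        # Bland: smallest improving index
    col <- tab[, pc]
    pos <- which(col > tol)
    if (!length(pos)) {
      ## cannot happen for bounded feasible problems; guard anyway
      return(list(tab = tab, basis = basis, status = "unbounded"))
    }
    ratios <- tab[pos, rhs_col] / col[pos]
    best <- pos[ratios <= min(ratios) + tol]
    pr <- best[which.min(basis[best])]   # Bland tie-break
    res <- lp_pivot(tab, basis, pr, pc)
    tab <- res$tab
    basis <- res$basis
  }
  list(tab = tab, basis = basis, status = "iterlimit")
}

#' Solve a box-constrained LP (dense two-phase simplex)
#'
#' Maximizes `c'x` subject to `A x = b` and `0 <= x <= u`.
#'
#' @param cvec Objective coefficients (length n).
#' @param A Equality constraint matrix (m x n; may have zero rows).
#' @param b Right-hand side (length m).
#' @param u Upper bounds (length n, non-negative, finite).
#' @param tol Numerical tolerance.
#' @return List with `status` ("optimal", "infeasible", or "iterlimit"),
#'   `value`, and the primal solution `x`.
#' @keywords internal
lp_bounded_max <- function(cvec, A, b, u, tol = 1e-9) {
  n <- length(cvec)
  A <- matrix(as.numeric(A), ncol = n)
  m <- nrow(A)
  stopifnot(length(b) == m, length(u) == n, all(u >= -tol), all(is.finite(u)))
  u <- pmax(u, 0)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  ## columns: x (1..n), bound slacks (n+1..2n), artificials (2n+1..2n+m)
  n_all <- 2L * n + m
  tab <- matrix(0, m + n, n_all + 1L)
  if (m > 0L) {
    tab[seq_len(m), seq_len(n)] <- A
    tab[cbind(seq_len(m), 2L * n + seq_len(m))] <- 1
    tab[seq_len(m), n_all + 1L] <- b
  }
  tab[m + seq_len(n), seq_len(n)] <- diag(n)
  tab[cbind(m + seq_len(n), n + seq_len(n))] <- 1
  tab[m + seq_len(n), n_all + 1L] <- u
  basis <- c(if (m > 0L) 2L * n + seq_len(m), n + seq_len(n))

  ## phase 1: drive artificials to zero
  if (m > 0L) {
    cost1 <- c(rep(0, 2L * n), rep(-1, m))
    res <- lp_iterate(tab, basis, cost1, active = seq_len(n_all), tol = tol)
    if (res$status != "optimal") return(list(status = res$status, value = NA_real_, x = NULL))
    tab <- res$tab
    basis <- res$basis
    if (sum(tab[basis > 2L * n, n_all + 1L]) > 1e-7) {
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    }
    ## pivot any degenerate artificial out of the basis, or drop its row
    drop_rows <- integer(0)
    for (r in seq_along(basis)) {
      if (basis[r] > 2L * n) {
        pc <- which(abs(tab[r, seq_len(2L * n)]) > tol)[1L]
        if (is.na(pc)) {
          drop_rows <- c(drop_rows, r)
        } else {
          res <- lp_pivot(tab, basis, r, pc)
          tab <- res$tab
          basis <- res$basis
        }
      }
    }
    if (length(drop_rows)) {
      tab <- tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }

  ## phase 2
  cost2 <- c(cvec, rep(0, n), rep(0, m))
  res <- lp_iterate(tab, basis, cost2, active = seq_len(2L * n), tol = tol)
  if (res$status != "optimal") return(list(status = res$status, value = NA_real_, x = NULL))
  tab <- res$tab
  basis <- res$basis
  x <- numeric(n)
  in_x <- basis <= n
  x[basis[in_x]] <- tab[which(in_x), ncol(tab)]
  list(status = "optimal", value = sum(cvec * x), x = x)
}
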