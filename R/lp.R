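# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Flux optimization problems here are small (tens of reactions) but routinely
# degenerate: knockouts pin fluxes to zero, alternate optima abound, and FVA
# pins the objective to its optimum face. A dense tableau simplex using
# Bland's smallest-index rule terminates on every such instance without
# cycling, at a cost that is irrelevant at this scale. Phase 1 minimizes
# artificial variables (detecting infeasibility); redundant rows whose
# artificial cannot be pivoted out are dropped before phase 2.
#
# Standard form solved by .simplex_core():
#   minimize  cost' z   subject to  A z = b,  z >= 0
# Callers encode flux bounds via variable shifting and explicit slack
# variables (see .solve_flux_lp in fba.R).

.SIMPLEX_TOL <- 1e-9

# one simplex run on a canonical tableau; allowed = columns permitted to enter
.simplex_iterate <- function(Tmat, basis, cost, allowed,
                             max_iter = 100000L) {
  n_col <- ncol(Tmat) - 1L
  rhs_col <- n_col + 1L
  for (iter in seq_len(max_iter)) {
    cb <- cost[basis]
    red <- cost[allowed] -
      as.numeric(crossprod(cb, Tmat[, allowed, drop = FALSE]))
    neg <- which(red < -.SIMPLEX_TOL)
    if (length(neg) == 0) {
      return(list(Tmat = Tmat, basis = basis, status = "optimal"))
    }
    j <- allowed[min(neg)] # Bland: smallest index enters
    col <- Tmat[, j]
    pos <- which(col > .SIMPLEX_TOL)
    if (length(pos) == 0) {
      return(list(Tmat = Tmat, basis = basis, status = "unbounded"))
    }
    ratios <- Tmat[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + .SIMPLEX_TOL]
    i <- cand[which.min(basis[cand])] # Bland: smallest basic index leaves
    piv <- Tmat[i, ] / Tmat[i, j]
    Tmat <- Tmat - outer(Tmat[, j], piv)
    Tmat[i, ] <- piv
    basis[i] <- j
  }
  list(Tmat = Tmat, basis = basis, status = "iteration_limit")
}

# minimize cost' z st A z = b, z >= 0
.simplex_core <- function(cost, A, b) {
  m <- nrow(A)
  n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # phase 1: artificials n+1 .. n+m form the initial identity basis
  Tmat <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- .simplex_iterate(Tmat, basis, cost1, allowed = seq_len(n + m))
  if (p1$status != "optimal") return(list(status = "infeasible"))
  resid <- sum(p1$Tmat[, n + m + 1L][p1$basis > n])
  if (resid > 1e-7) return(list(status = "infeasible"))
  Tmat <- p1$Tmat
  basis <- p1$basis
  # pivot remaining zero-valued artificials out; drop redundant rows
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    structural <- which(abs(Tmat[i, seq_len(n)]) > .SIMPLEX_TOL)
    if (length(structural) == 0) {
      drop_rows <- c(drop_rows, i)
      next
    }
    j <- structural[1]
    piv <- Tmat[i, ] / Tmat[i, j]
    Tmat <- Tmat - outer(Tmat[, j], piv)
    Tmat[i, ] <- piv
    basis[i] <- j
  }
  if (length(drop_rows)) {
    Tmat <- Tmat[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2: artificials may not re-enter
  cost2 <- c(cost, rep(0, m))
  p2 <- .simplex_iterate(Tmat, basis, cost2, allowed = seq_len(n))
  if (p2$status != "optimal") return(list(status = p2$status))
  z <- numeric(n + m)
  z[p2$basis] <- p2$Tmat[, ncol(p2$Tmat)]
  z <- z[seq_len(n)]
  list(status = "optimal", z = z, value = sum(cost * z))
}
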