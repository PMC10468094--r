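## Internal linear programming for FBA-family problems:
##
##     maximise  c'v   s.t.  S v = 0,  lb <= v <= ub
##
## (finite box bounds; the equality system is always homogeneous -- the
## FVA objective-fraction constraint is expressed as a raised bound on the
## objective reaction, never as an extra row).
##
## Solution strategy, chosen to stay inside boot::simplex's reliable
## single-phase code path (its two-phase/artificial-variable path
## mishandles the degenerate bases that homogeneous equalities always
## produce):
##   1. fixed variables (lb == ub, mostly blocked reactions) are pinned
##      and dropped -- they would otherwise contribute zero-width box rows
##      that make the tableau maximally degenerate;
##   2. the steady-state equalities over the remaining free variables are
##      eliminated exactly through an orthonormal null-space basis N
##      (full SVD) around a feasible anchor v0 (0 for plain FBA, the FBA
##      optimum for FVA subproblems): every feasible flux is
##      v = v0 + N y on the free coordinates;
##   3. splitting y = y+ - y- gives a nonnegative-variable LP with only
##      <= rows and non-negative RHS, solved from the slack basis.

null_basis <- function(S, tol = 1e-9) {
  n <- ncol(S)
  if (n == 0) return(matrix(0, 0, 0))
  if (nrow(S) == 0) return(diag(n))
  sv <- svd(S, nu = 0, nv = n)
  d <- sv$d
  r <- sum(d > tol * max(d[1], 1))
  if (r >= n) matrix(0, n, 0) else sv$v[, (r + 1):n, drop = FALSE]
}

# Precompute the reduction for a family of problems sharing S, lb, ub
# (FVA, leak scans). Anchors and objectives may still vary per solve.
gsmn_lp_prep <- function(S, lb, ub) {
  free <- which(ub > lb)
  list(free = free, N = null_basis(S[, free, drop = FALSE]))
}

lp_fba <- function(obj, S, lb, ub, maximize = TRUE, v0 = NULL, prep = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (is.null(v0)) v0 <- rep(0, n)
  if (any(v0 < lb - 1e-7) || any(v0 > ub + 1e-7))
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  if (is.null(prep)) prep <- gsmn_lp_prep(S, lb, ub)
  free <- prep$free; N <- prep$N
  k <- ncol(N)
  if (k == 0)   # trivial null space: v0 is the only feasible flux
    return(list(status = "optimal", objective = sum(obj * v0), solution = v0))
  cN <- as.vector(crossprod(N, obj[free]))
  a <- c(cN, -cN)
  A1 <- rbind(cbind(N, -N), cbind(-N, N))
  b1 <- pmax(c(ub[free] - v0[free], v0[free] - lb[free]), 0)
  res <- suppressWarnings(boot::simplex(a = a, A1 = A1, b1 = b1,
                                        maxi = maximize,
                                        n.iter = max(500L, 60L * k),
                                        eps = 1e-10))
  if (res$solved == -1)
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  y <- res$soln[seq_len(k)] - res$soln[k + seq_len(k)]
  v <- v0
  v[free] <- v0[free] + as.vector(N %*% y)
  v <- pmin(pmax(v, lb), ub)
  list(status = if (res$solved == 1) "optimal" else "iteration_limit",
       objective = sum(obj * v), solution = v)
}
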