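# Bounded-variable revised simplex for the flux-balance linear program
#
#   optimize  c'v   subject to  S v = b,  l <= v <= u   (l, u finite)
#
# Used by solve_fba(). Nonbasic variables rest on one of their bounds; the
# basis system is re-solved from scratch every iteration (dense LU via
# solve()), so numerical error does not accumulate the way it does in a
# tableau method. Phase 1 drives a set of signed artificial columns to
# zero; afterwards the artificials are frozen at zero rather than pivoted
# out, which handles rank-deficient S (redundant mass-balance rows)
# without special cases. Dantzig pricing switches to Bland's rule after a
# stall, guarding against cycling on the degenerate LPs metabolic
# networks produce.

.lp_box <- function(obj, S, lower, upper, maximize = TRUE, b = NULL,
                    tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  m <- nrow(S)
  stopifnot(ncol(S) == n, length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("all bounds must be finite (apply an unbounded cap first)")
  if (any(lower > upper))
    stop("lower bound exceeds upper bound")
  if (is.null(b)) b <- numeric(m)

  # scale equality rows to unit max coefficient
  rs <- apply(abs(S), 1L, max)
  rs[rs < 1e-300] <- 1
  S <- S / rs
  b <- b / rs

  ntot <- n + m
  # structural variables start at the bound nearest zero
  x <- ifelse(abs(lower) <= abs(upper), lower, upper)
  vstat <- ifelse(abs(lower) <= abs(upper), -1L, 1L)  # -1 lower, +1 upper
  resid <- b - as.numeric(S %*% x)
  sgn <- ifelse(resid >= 0, 1, -1)
  A <- cbind(S, diag(sgn, nrow = m))
  lo <- c(lower, rep(0, m))
  hi <- c(upper, rep(Inf, m))
  x <- c(x, abs(resid))
  vstat <- c(vstat, rep(0L, m))        # artificials basic
  basis <- n + seq_len(m)

  cost <- c(rep(0, n), rep(1, m))      # phase-1 cost
  phase <- 1L
  sense <- if (maximize) -1 else 1
  iters <- 0L
  stall <- 0L
  last_obj <- Inf

  feas_tol <- 1e-9 * (1 + max(abs(b), 1))
  repeat {
    if (iters >= max_iter)
      return(list(status = "maxiter", objective = NA_real_, x = NULL,
                  iterations = iters))
    if (phase == 1L && sum(x[(n + 1L):ntot]) <= feas_tol) {
      # feasible: freeze artificials at zero and switch objectives
      hi[(n + 1L):ntot] <- 0
      x[(n + 1L):ntot] <- 0
      cost <- c(sense * obj, rep(0, m))
      phase <- 2L
      stall <- 0L
      last_obj <- Inf
    }
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]),
                  error = function(e) NULL)
    if (is.null(y))
      return(list(status = "singular", objective = NA_real_, x = NULL,
                  iterations = iters))
    dvec <- cost - as.numeric(crossprod(A, y))
    nb <- which(vstat != 0L)
    dtol <- tol * (1 + max(abs(cost)))
    elig <- nb[(vstat[nb] == -1L & dvec[nb] < -dtol) |
               (vstat[nb] == 1L & dvec[nb] > dtol)]
    if (length(elig) == 0L) {
      # phase optimal
      if (phase == 1L) {
        if (sum(x[(n + 1L):ntot]) > 1e-6 * (1 + max(abs(b), 1)))
          return(list(status = "infeasible", objective = NA_real_,
                      x = NULL, iterations = iters))
        # within roundoff of feasible: clamp and continue in phase 2
        hi[(n + 1L):ntot] <- 0
        x[(n + 1L):ntot] <- 0
        cost <- c(sense * obj, rep(0, m))
        phase <- 2L
        stall <- 0L
        last_obj <- Inf
        next
      }
      # refinement: clamp nonbasic variables exactly onto their bounds and
      # re-solve for the basic values, removing any accumulated drift
      nbv <- which(vstat != 0L)
      x[nbv] <- ifelse(vstat[nbv] == -1L, lo[nbv], hi[nbv])
      rhs <- b - as.numeric(A[, nbv, drop = FALSE] %*% x[nbv])
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (!is.null(xb)) x[basis] <- xb
      xs <- x[seq_len(n)]
      bval <- x[basis]
      return(list(status = "optimal",
                  objective = sum(obj * xs),
                  x = xs,
                  degenerate = any(abs(bval - lo[basis]) < 1e-8 |
                                   abs(bval - hi[basis]) < 1e-8),
                  iterations = iters))
    }
    bland <- stall > 2L * m + 50L
    j <- if (bland) min(elig)
         else elig[which.max(abs(dvec[elig]))]
    s <- if (vstat[j] == -1L) 1 else -1        # direction of x_j
    w <- tryCatch(solve(B, A[, j]), error = function(e) NULL)
    if (is.null(w))
      return(list(status = "singular", objective = NA_real_, x = NULL,
                  iterations = iters))
    delta <- -s * w                            # change of x_B per unit t
    piv_tol <- tol
    bset <- basis
    ti <- rep(Inf, m)
    up <- delta > piv_tol
    dn <- delta < -piv_tol
    ti[up] <- (hi[bset[up]] - x[bset[up]]) / delta[up]
    ti[dn] <- (lo[bset[dn]] - x[bset[dn]]) / delta[dn]
    ti[ti < 0] <- 0                            # roundoff past a bound
    tmax <- hi[j] - lo[j]                      # bound-to-bound flip
    tlim <- min(ti, tmax)
    if (!is.finite(tlim))
      return(list(status = "unbounded", objective = NA_real_, x = NULL,
                  iterations = iters))
    leave <- 0L
    if (tlim < tmax - tol) {
      near <- which(ti <= tlim + tol * (1 + tlim))
      leave <- if (bland) near[which.min(bset[near])]  # Bland: lowest index
               else near[which.max(abs(delta[near]))]  # largest pivot
      tlim <- ti[leave]
    }
    # apply the step
    x[j] <- x[j] + s * tlim
    x[basis] <- x[basis] + delta * tlim
    if (leave == 0L) {
      vstat[j] <- -vstat[j]                    # flipped to other bound
    } else {
      bi <- basis[leave]
      hit_hi <- delta[leave] > 0
      x[bi] <- if (hit_hi) hi[bi] else lo[bi]
      vstat[bi] <- if (hit_hi) 1L else -1L
      basis[leave] <- j
      vstat[j] <- 0L
    }
    iters <- iters + 1L
    pobj <- sum(cost * x)
    if (pobj < last_obj - dtol) { last_obj <- pobj; stall <- 0L }
    else stall <- stall + 1L
  }
}
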