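## Dense two-phase primal simplex for LPs with bounded variables:
##
##     minimize  c'x   subject to  A x = b,  lb <= x <= ub.
##
## All metabolic LPs in this package are small (tens of metabolites, at most a
## few hundred variables after splitting reversible reactions), so a dense
## implementation with refactorization at every iteration is both fast enough
## and numerically robust. The pivot rule is Dantzig's with smallest-index
## tie-breaking, switching permanently to Bland's rule after a run of
## degenerate pivots so that termination is guaranteed; together with the
## fixed initial basis this makes repeated solves bitwise deterministic.

## Entering-variable tolerance on reduced costs; pivots smaller than .tolPiv
## are treated as structural zeros in the ratio test.
.tolD <- 1e-9
.tolPiv <- 1e-10

#' @noRd
.lpSolve <- function(obj, Aeq, beq, lb, ub, maximize = FALSE,
                     maxit = 50000L) {
  Aeq <- as.matrix(Aeq)
  m <- nrow(Aeq)
  n <- ncol(Aeq)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(beq) == m)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))
  if (n == 0L) {
    feas <- (m == 0L) || all(abs(beq) <= 1e-9)
    return(list(status = if (feas) "optimal" else "infeasible",
                x = numeric(0), objval = 0))
  }
  cc <- if (maximize) -obj else obj

  ## Work on the augmented system [A | signed identity]; the artificial block
  ## gives a feasible starting basis for phase 1.
  N <- n + m
  atUpper <- logical(N)
  x <- numeric(N)
  ## Nonbasic structural variables start at the finite bound nearer zero.
  startUpper <- is.infinite(lb[seq_len(n)]) |
    (is.finite(ub[seq_len(n)]) & abs(ub[seq_len(n)]) < abs(lb[seq_len(n)]))
  atUpper[seq_len(n)] <- startUpper
  x[seq_len(n)] <- ifelse(startUpper, ub, lb)
  if (any(!is.finite(x[seq_len(n)])))
    stop("each variable needs at least one finite bound")

  resid <- beq - drop(Aeq %*% x[seq_len(n)])
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(Aeq, diag(sgn, nrow = m, ncol = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  x[n + seq_len(m)] <- abs(resid)
  basis <- n + seq_len(m)

  bscale <- max(1, abs(beq))

  runPhase <- function(cvec, basis, x, atUpper, lbf, ubf) {
    degenRun <- 0L
    bland <- FALSE
    for (it in seq_len(maxit)) {
      Bmat <- Afull[, basis, drop = FALSE]
      nonbas <- setdiff(seq_len(N), basis)
      xN <- x[nonbas]
      xB <- tryCatch(solve(Bmat, beq - drop(Afull[, nonbas, drop = FALSE] %*% xN)),
                     error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular"))
      x[basis] <- xB
      y <- solve(t(Bmat), cvec[basis])
      d <- cvec[nonbas] - drop(t(Afull[, nonbas, drop = FALSE]) %*% y)

      incr <- !atUpper[nonbas] & d < -.tolD          # at lower bound, wants up
      decr <- atUpper[nonbas] & d > .tolD            # at upper bound, wants down
      elig <- which(incr | decr)
      if (length(elig) == 0L)
        return(list(status = "optimal", basis = basis, x = x,
                    atUpper = atUpper))
      if (bland) {
        pick <- elig[which.min(nonbas[elig])]
      } else {
        pick <- elig[which.max(abs(d[elig]))]
        if (sum(abs(d[elig]) == abs(d[pick])) > 1L)
          pick <- elig[abs(d[elig]) == abs(d[pick])][1L]
      }
      j <- nonbas[pick]
      s <- if (atUpper[j]) -1 else 1                  # direction of x_j
      w <- drop(solve(Bmat, Afull[, j]))
      stepB <- -s * w                                 # xB moves by stepB * t

      tmax <- ubf[j] - lbf[j]                        # entering var's own range
      tbasic <- Inf
      leave <- 0L
      for (i in seq_len(m)) {
        if (stepB[i] > .tolPiv) {
          ti <- (ubf[basis[i]] - x[basis[i]]) / stepB[i]
        } else if (stepB[i] < -.tolPiv) {
          ti <- (lbf[basis[i]] - x[basis[i]]) / stepB[i]
        } else next
        ti <- max(ti, 0)
        if (ti < tbasic - 1e-12 ||
            (abs(ti - tbasic) <= 1e-12 && leave > 0L &&
             basis[i] < basis[leave])) {
          tbasic <- ti
          leave <- i
        }
      }
      tstep <- min(tmax, tbasic)
      if (!is.finite(tstep)) return(list(status = "unbounded"))

      if (tstep <= 1e-11) degenRun <- degenRun + 1L else degenRun <- 0L
      if (degenRun > 2L * N) bland <- TRUE

      if (tmax <= tbasic) {
        ## bound flip: entering variable runs to its opposite bound
        x[basis] <- x[basis] + stepB * tmax
        x[j] <- if (atUpper[j]) lbf[j] else ubf[j]
        atUpper[j] <- !atUpper[j]
        next
      }
      ## pivot
      lv <- basis[leave]
      x[j] <- x[j] + s * tbasic
      x[basis] <- x[basis] + stepB * tbasic
      hitUpper <- stepB[leave] > 0
      x[lv] <- if (hitUpper) ubf[lv] else lbf[lv]
      atUpper[lv] <- hitUpper
      basis[leave] <- j
    }
    list(status = "maxit")
  }

  ## phase 1: drive the artificial variables to zero
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- runPhase(c1, basis, x, atUpper, lbf, ubf)
  if (!identical(p1$status, "optimal"))
    return(list(status = p1$status, x = rep(NA_real_, n), objval = NA_real_))
  art <- p1$x[n + seq_len(m)]
  if (sum(art) > 1e-7 * bscale)
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))

  ## phase 2: artificials pinned at zero, original objective
  ubf[n + seq_len(m)] <- 0
  x2 <- p1$x
  x2[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  p2 <- runPhase(c2, p1$basis, x2, p1$atUpper, lbf, ubf)
  if (!identical(p2$status, "optimal"))
    return(list(status = p2$status, x = rep(NA_real_, n), objval = NA_real_))

  xsol <- p2$x[seq_len(n)]
  ## clamp round-off outside the box
  xsol <- pmin(pmax(xsol, lb), ub)
  obj2 <- sum(obj * xsol)
  list(status = "optimal", x = xsol, objval = obj2)
}
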