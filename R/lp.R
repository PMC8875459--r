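## Dense bounded-variable two-phase primal simplex.
##
## All flux LPs in this package (FBA, FVA, the consistency and extraction
## subproblems) are small and dense: max c'x subject to A x = b and
## l <= x <= u with finite bounds. Bland's anti-cycling rule is used
## throughout, which guarantees termination at the cost of a few extra
## pivots -- irrelevant at these problem sizes.

.LP_BIG <- 1e6          # stand-in for an infinite bound
.LP_TOL <- 1e-9         # optimality / feasibility tolerance

#' Solve a bounded linear program
#'
#' Maximises (or minimises) \code{obj \%*\% x} subject to \code{A \%*\% x = b}
#' and \code{lb <= x <= ub}. Infinite bounds are clamped to \code{1e6}; the
#' steady-state flux problems solved here are always bounded once reaction
#' bounds are finite.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense or sparse constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n).
#' @param maximize logical; maximise (default) or minimise.
#' @return A list with elements \code{status} (\code{"optimal"} or
#'   \code{"infeasible"}), \code{objective} and \code{x}.
#' @examples
#' # max x2 s.t. x1 - x2 = 0, 0 <= x <= c(5, 10)  ->  5
#' solveLP(c(0, 1), matrix(c(1, -1), 1), 0, c(0, 0), c(5, 10))$objective
#' @export
solveLP <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  lb <- pmax(lb, -.LP_BIG); ub <- pmin(ub, .LP_BIG)
  if (any(lb > ub + .LP_TOL))
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  ub <- pmax(ub, lb)
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## start nonbasic at the bound closer to zero; artificials absorb residual
  start <- ifelse(abs(lb) <= abs(ub), lb, ub)
  resid <- as.numeric(b - A %*% start)
  sg <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  N <- n + m
  lbf <- c(lb, rep(0, m)); ubf <- c(ub, rep(.LP_BIG, m))

  state <- list(
    basis = (n + 1L):N,                  # artificials basic
    atub = logical(N),                   # nonbasic-at-upper flags
    A = Afull, lb = lbf, ub = ubf
  )
  state$atub[seq_len(n)] <- abs(ub) < abs(lb)

  ## phase 1: minimise sum of artificials
  c1 <- c(rep(0, n), rep(-1, m))
  state <- .simplexIterate(state, c1, b, allowed = seq_len(N))
  xB <- .basicValues(state, b)
  p1 <- sum(.fullX(state, xB)[(n + 1L):N])
  if (p1 > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))

  ## phase 2: artificials frozen at zero, excluded from entering
  state$ub[(n + 1L):N] <- 0
  state$lb[(n + 1L):N] <- 0
  c2 <- c(cc, rep(0, m))
  state <- .simplexIterate(state, c2, b, allowed = seq_len(n))
  xB <- .basicValues(state, b)
  x <- .fullX(state, xB)[seq_len(n)]
  objective <- sum(as.numeric(obj) * x)
  list(status = "optimal", objective = objective, x = x)
}

.fullX <- function(state, xB) {
  x <- ifelse(state$atub, state$ub, state$lb)
  x[state$basis] <- xB
  x
}

.basicValues <- function(state, b) {
  nonb <- setdiff(seq_len(ncol(state$A)), state$basis)
  xN <- ifelse(state$atub[nonb], state$ub[nonb], state$lb[nonb])
  rhs <- b - state$A[, nonb, drop = FALSE] %*% xN
  as.numeric(solve(state$A[, state$basis, drop = FALSE], rhs))
}

## One run of the bounded-variable simplex with Bland's rule.
## `allowed`: indices eligible to enter the basis.
.simplexIterate <- function(state, cc, b, allowed, maxit = 20000L) {
  A <- state$A
  N <- ncol(A)
  tol <- .LP_TOL
  for (it in seq_len(maxit)) {
    basis <- state$basis
    B <- A[, basis, drop = FALSE]
    xB <- .basicValues(state, b)
    y <- solve(t(B), cc[basis])
    nonb <- setdiff(allowed, basis)
    if (length(nonb) == 0L) return(state)
    d <- cc[nonb] - as.numeric(crossprod(A[, nonb, drop = FALSE], y))
    atub <- state$atub[nonb]
    improving <- (d > tol & !atub) | (d < -tol & atub)
    if (!any(improving)) return(state)
    j <- nonb[improving][which.min(nonb[improving])]   # Bland: smallest index
    s <- if (state$atub[j]) -1 else 1                  # direction of change
    w <- as.numeric(solve(B, A[, j]))

    ## ratio test: basic vars hitting a bound, or entering var flipping bound
    dxB <- -s * w
    tmax <- state$ub[j] - state$lb[j]                  # bound flip distance
    leave <- 0L                                        # 0 => bound flip
    for (i in seq_along(basis)) {
      if (dxB[i] < -tol) {
        ti <- (xB[i] - state$lb[basis[i]]) / (-dxB[i]); hit_ub <- FALSE
      } else if (dxB[i] > tol) {
        ti <- (state$ub[basis[i]] - xB[i]) / dxB[i]; hit_ub <- TRUE
      } else next
      if (ti < tmax - tol ||
          (ti < tmax + tol && (leave == 0L || basis[i] < basis[leave]))) {
        tmax <- ti; leave <- i; leave_ub <- hit_ub
      }
    }
    if (tmax >= .LP_BIG) return(state)                 # cannot happen: finite bounds
    if (leave == 0L) {
      state$atub[j] <- !state$atub[j]                  # bound flip, basis unchanged
    } else {
      lv <- basis[leave]
      state$atub[lv] <- leave_ub
      state$basis[leave] <- j
      ## entering variable leaves its bound
      state$atub[j] <- FALSE
    }
  }
  stop("simplex iteration limit reached")
}

#' Brute-force LP oracle by basic-solution enumeration
#'
#' Enumerates every basic solution (choice of m basic columns, remaining
#' variables fixed at either bound), keeps the feasible ones, and returns the
#' best objective. Exponential -- intended as an independent check of
#' \code{\link{solveLP}} on networks of a handful of reactions.
#'
#' @inheritParams solveLP
#' @return list with \code{objective} (NA if infeasible) and \code{x}.
#' @export
enumerateLP <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  lb <- pmax(lb, -.LP_BIG); ub <- pmin(ub, .LP_BIG)
  best <- NULL; bestval <- if (maximize) -Inf else Inf
  feasible <- function(x) {
    all(x >= lb - 1e-7) && all(x <= ub + 1e-7) &&
      max(abs(A %*% x - b)) < 1e-7
  }
  consider <- function(x) {
    if (!feasible(x)) return()
    v <- sum(obj * x)
    if ((maximize && v > bestval) || (!maximize && v < bestval)) {
      bestval <<- v; best <<- x
    }
  }
  ## enumerate over a maximal independent row subset (rank-deficient
  ## systems -- e.g. orphan metabolites -- have no invertible m-basis)
  if (m > 0L) {
    qrA <- qr(t(A))
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    A_red <- A[keep, , drop = FALSE]
    b_red <- b[keep]
  }
  if (m == 0L) {
    consider(ifelse((obj >= 0) == maximize, ub, lb))
  } else {
    m_red <- nrow(A_red)
    sets <- utils::combn(n, min(m_red, n), simplify = FALSE)
    for (Bset in sets) {
      Bmat <- A_red[, Bset, drop = FALSE]
      if (abs(det(Bmat)) < 1e-10) next
      Nset <- setdiff(seq_len(n), Bset)
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(Nset)))
      if (length(Nset) == 0L) grid <- data.frame(row.names = 1)
      for (g in seq_len(nrow(grid))) {
        x <- numeric(n)
        if (length(Nset))
          x[Nset] <- ifelse(unlist(grid[g, ]), ub[Nset], lb[Nset])
        rhs <- b_red - if (length(Nset))
          A_red[, Nset, drop = FALSE] %*% x[Nset] else b_red * 0
        x[Bset] <- as.numeric(solve(Bmat, rhs))
        consider(x)   # feasibility checked against the FULL system
      }
    }
  }
  if (is.null(best)) list(objective = NA_real_, x = rep(NA_real_, n))
  else list(objective = bestval, x = best)
}
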