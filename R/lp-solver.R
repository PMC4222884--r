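#' @include model-build.R
NULL

## Dense bounded-variable two-phase primal simplex.
##
## Solves  min/max  c'x   s.t.  A x = b,  l <= x <= u.
##
## Scale target: constraint-based core models (tens of rows/columns) and the
## split-variable problems derived from them, where a dense factor-per-
## iteration simplex is fast and, more importantly, deterministic and easy to
## audit. The basis system is re-solved from scratch every iteration, so
## steady-state residuals stay at machine precision. Dantzig pricing with a
## Bland fallback guards against cycling on degenerate vertices.

.LP_TOL <- 1e-9
.LP_BIG <- 1e6

#' Solve a bounded linear program
#'
#' @param A constraint matrix (dense or sparse), one row per equality.
#' @param b right-hand side vector.
#' @param cvec objective coefficient vector.
#' @param lb,ub variable bounds; infinite bounds are clamped to \code{1e6}
#'   internally and a solution resting on a clamped bound is reported as
#'   \code{"unbounded"}.
#' @param maximize maximize instead of minimize.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{objective} and the primal vector \code{x}.
#' @export
solveLP <- function(A, b, cvec, lb, ub, maximize = FALSE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  infLo <- !is.finite(lb); infHi <- !is.finite(ub)
  lb[infLo] <- -.LP_BIG; ub[infHi] <- .LP_BIG
  cc <- if (maximize) -cvec else cvec

  ## phase 1: artificials, one per row
  nTot <- n + m
  Afull <- cbind(A, diag(1, m))
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)   # nonbasic start at nearer bound
  r <- b - as.vector(A %*% x)
  for (i in seq_len(m)) if (r[i] < 0) Afull[i, n + i] <- -1
  lbF <- c(lb, rep(0, m)); ubF <- c(ub, rep(Inf, m))
  status0 <- ifelse(abs(lb) <= abs(ub), -1L, 1L)    # -1 at lower, +1 at upper
  basis <- (n + 1L):(n + m)
  nbStatus <- c(status0, rep(0L, m))                # 0 = basic placeholder
  phase1 <- .simplexRun(Afull, b, c(rep(0, n), rep(1, m)), lbF, ubF,
                        basis, nbStatus)
  if (phase1$status != "optimal" || phase1$objective > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  ## pin artificials at zero and run phase 2 on the original objective
  lbF2 <- lbF; ubF2 <- ubF
  lbF2[(n + 1L):nTot] <- 0; ubF2[(n + 1L):nTot] <- 0
  phase2 <- .simplexRun(Afull, b, c(cc, rep(0, m)), lbF2, ubF2,
                        phase1$basis, phase1$nbStatus)
  if (phase2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  xOut <- phase2$x[seq_len(n)]
  hitClamp <- (infLo & xOut < -.LP_BIG + 1e-3) | (infHi & xOut > .LP_BIG - 1e-3)
  if (any(hitClamp))
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  obj <- sum(cvec * xOut)
  list(status = "optimal", objective = obj, x = xOut)
}

.simplexRun <- function(A, b, cc, lb, ub, basis, nbStatus, maxIter = 50000L) {
  m <- nrow(A); n <- ncol(A)
  ub[!is.finite(ub)] <- .LP_BIG * 10
  lb[!is.finite(lb)] <- -.LP_BIG * 10
  nbStatus[basis] <- 0L
  blandFrom <- 2000L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter)
      stop(errorCondition("simplex iteration limit exceeded",
                          class = c("solverError", "acetofluxError")))
    nonbasic <- which(nbStatus != 0L)
    xN <- ifelse(nbStatus[nonbasic] == -1L, lb[nonbasic], ub[nonbasic])
    Bmat <- A[, basis, drop = FALSE]
    xB <- tryCatch(solve(Bmat, b - A[, nonbasic, drop = FALSE] %*% xN),
                   error = function(e)
                     stop(errorCondition("singular simplex basis",
                          class = c("solverError", "acetofluxError"))))
    xB <- as.vector(xB)
    y <- as.vector(solve(t(Bmat), cc[basis]))
    dN <- cc[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))
    viol <- ifelse(nbStatus[nonbasic] == -1L, -dN, dN)
    cand <- which(viol > .LP_TOL)
    if (!length(cand)) {
      x <- numeric(n); x[nonbasic] <- xN; x[basis] <- xB
      return(list(status = "optimal", objective = sum(cc * x), x = x,
                  basis = basis, nbStatus = nbStatus))
    }
    pick <- if (iter > blandFrom) cand[which.min(nonbasic[cand])]
            else cand[which.max(viol[cand])]
    enter <- nonbasic[pick]
    fromLower <- nbStatus[enter] == -1L
    w <- as.vector(solve(Bmat, A[, enter]))
    ## movement t >= 0 of the entering variable away from its bound;
    ## basic values change by -w t (from lower) or +w t (from upper)
    delta <- if (fromLower) -w else w
    tMax <- ub[enter] - lb[enter]
    leave <- 0L; leaveBound <- 0L
    for (i in seq_len(m)) {
      if (delta[i] > 1e-10) {
        ti <- (ub[basis[i]] - xB[i]) / delta[i]; bi <- 1L
      } else if (delta[i] < -1e-10) {
        ti <- (lb[basis[i]] - xB[i]) / delta[i]; bi <- -1L
      } else next
      ti <- max(ti, 0)
      if (ti < tMax - 1e-10 ||
          (ti < tMax + 1e-10 && leave > 0L &&
           abs(delta[i]) > abs(delta[leave]) + 1e-12)) {
        if (ti < tMax - 1e-10) { leave <- i; leaveBound <- bi; tMax <- ti }
        else { leave <- i; leaveBound <- bi }
      }
    }
    if (!is.finite(tMax))
      return(list(status = "unbounded", objective = NA_real_, x = NULL,
                  basis = basis, nbStatus = nbStatus))
    if (leave == 0L) {
      ## bound flip of the entering variable
      nbStatus[enter] <- -nbStatus[enter]
    } else {
      out <- basis[leave]
      basis[leave] <- enter
      nbStatus[enter] <- 0L
      nbStatus[out] <- leaveBound
    }
  }
}

#' Solve a flux LP on a model
#'
#' Low-level entry used by [fba()] and friends: optimizes \code{cvec' v}
#' subject to the steady-state constraint \code{S v = 0}, optional extra
#' linear rows, and the model's flux bounds.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param cvec named or positional objective over reactions.
#' @param maximize direction.
#' @param extraRows optional list of lists \code{list(coef = named vector,
#'   rhs = value)} appended as equality rows (used for objective-fixing).
#' @return list as from [solveLP()], with \code{x} named by reaction id.
#' @keywords internal
.modelLP <- function(model, cvec, maximize = TRUE, extraRows = NULL) {
  S <- as.matrix(model@stoichiometry)
  rxn <- model@reactions
  n <- nrow(rxn)
  if (!is.null(names(cvec))) {
    cfull <- stats::setNames(numeric(n), rxn$id)
    cfull[names(cvec)] <- cvec
  } else cfull <- cvec
  b <- rep(0, nrow(S))
  if (!is.null(extraRows)) {
    for (row in extraRows) {
      coef <- stats::setNames(numeric(n), rxn$id)
      coef[names(row$coef)] <- row$coef
      S <- rbind(S, coef)
      b <- c(b, row$rhs)
    }
  }
  res <- solveLP(S, b, cfull, rxn$lower, rxn$upper, maximize = maximize)
  if (!is.null(res$x)) names(res$x) <- rxn$id
  res
}
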