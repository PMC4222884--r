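#' @include fba.R
NULL

#' GapfillResult: one minimal reaction set restoring the objective
#'
#' @slot added ids of the universal-pool reactions added.
#' @slot restoredObjective objective value after addition.
#' @export
setClass("GapfillResult",
  representation(added = "character", restoredObjective = "numeric"))

setMethod("show", "GapfillResult", function(object) {
  cat(sprintf("GapfillResult: {%s} -> objective %.6g\n",
              paste(object@added, collapse = ", "),
              object@restoredObjective))
})

## LP relaxation of the gap-filling MILP at given binary fixings/bounds.
## Variables: [v (native+pool); y (pool); slack rows for v_j <= ub_j y_j and
## v_j >= lb_j y_j; slack per integer cut]. Minimizes sum(y).
.gapfillRelaxation <- function(S, lb, ub, poolIdx, objIdx, minObjective,
                               yLo, yHi, cuts) {
  m <- nrow(S); n <- ncol(S); k <- length(poolIdx)
  nCut <- length(cuts)
  ## columns: v (n), y (k), sUp (k), sLo (k), sCut (nCut)
  nv <- n + 3 * k + nCut
  A <- matrix(0, m + 2 * k + nCut, nv)
  A[seq_len(m), seq_len(n)] <- S
  b <- rep(0, m + 2 * k + nCut)
  for (t in seq_len(k)) {
    j <- poolIdx[t]
    r1 <- m + t                      # v_j - ub_j y_t + sUp_t = 0
    A[r1, j] <- 1; A[r1, n + t] <- -ub[j]; A[r1, n + k + t] <- 1
    r2 <- m + k + t                  # v_j - lb_j y_t - sLo_t = 0
    A[r2, j] <- 1; A[r2, n + t] <- -lb[j]; A[r2, n + 2 * k + t] <- -1
  }
  for (ci in seq_along(cuts)) {
    r <- m + 2 * k + ci              # sum_{t in cut} y_t + s = |cut| - 1
    A[r, n + cuts[[ci]]] <- 1
    A[r, n + 3 * k + ci] <- 1
    b[r] <- length(cuts[[ci]]) - 1L
  }
  lbv <- c(lb, yLo, rep(0, 2 * k + nCut))
  ubv <- c(ub, yHi, rep(Inf, 2 * k + nCut))
  lbv[objIdx] <- max(lbv[objIdx], minObjective)
  cvec <- c(rep(0, n), rep(1, k), rep(0, 2 * k + nCut))
  res <- solveLP(A, b, cvec, lbv, ubv, maximize = FALSE)
  if (res$status == "optimal") res$y <- res$x[n + seq_len(k)]
  res
}

.gapfillBnB <- function(S, lb, ub, poolIdx, objIdx, minObjective, cuts,
                        bestCap = Inf) {
  k <- length(poolIdx)
  ## with big-M activation constraints the relaxation can satisfy the
  ## producibility threshold with y as small as minObjective / M, so the
  ## integrality tolerance must sit strictly below that ratio
  bigM <- max(abs(ub[poolIdx]), abs(lb[poolIdx]), 1)
  intTol <- min(1e-8, minObjective / (2 * bigM))
  best <- NULL; bestObj <- bestCap
  nodes <- 0L
  stack <- list(list(lo = rep(0, k), hi = rep(1, k)))
  while (length(stack)) {
    nodes <- nodes + 1L
    if (nodes > 50000L)
      stop(errorCondition("gap-fill branch-and-bound node limit exceeded",
                          class = c("solverError", "acetofluxError")))
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- .gapfillRelaxation(S, lb, ub, poolIdx, objIdx, minObjective,
                              node$lo, node$hi, cuts)
    if (rel$status != "optimal") next
    if (rel$objective > bestObj - 1e-6) next
    y <- pmin(pmax(rel$y, 0), 1)
    frac <- which(y > intTol & y < 1 - intTol)
    if (!length(frac)) {
      sel <- which(y > 0.5)
      if (length(sel) < bestObj - 1e-6) {
        best <- sel; bestObj <- length(sel)
      }
      next
    }
    br <- frac[which.max(pmin(y[frac], 1 - y[frac]))]
    n1 <- node; n1$lo[br] <- 1
    n0 <- node; n0$hi[br] <- 0
    stack[[length(stack) + 1L]] <- n0
    stack[[length(stack) + 1L]] <- n1
  }
  list(selection = best, size = if (is.null(best)) NA_real_ else bestObj)
}

#' SMILEY-style gap-filling
#'
#' Finds minimal sets of reactions from a universal pool whose addition to
#' the model restores producibility of the objective (objective flux at
#' least \code{minObjective}). The selection is a cardinality-minimizing
#' mixed-integer program (binary activation per pool reaction) solved by
#' branch-and-bound on the LP relaxation; alternate minimal sets are
#' enumerated with integer cuts. Every returned set is a minimality witness:
#' removing any single member drops the objective below the threshold again.
#'
#' @param model a \linkS4class{MetabolicModel} whose objective is currently
#'   blocked.
#' @param universal list of [reaction()] descriptions forming the pool
#'   (ids must not collide with model reactions).
#' @param objective reaction id to restore (default model objective).
#' @param minObjective producibility threshold (default 1e-3).
#' @param maxSolutions maximal number of distinct minimal sets to enumerate
#'   (default 1; \code{Inf} for all of minimal cardinality).
#' @param metabolites optional data.frame of additional metabolites used by
#'   pool reactions.
#' @return list of \linkS4class{GapfillResult}; a single result with an
#'   empty \code{added} set when the model already meets the threshold.
#' @export
gapfill <- function(model, universal, objective = NULL, minObjective = 1e-3,
                    maxSolutions = 1, metabolites = NULL) {
  objective <- objective %||%
    (if (length(model@objective)) model@objective else
       .err("no objective to restore", "referenceError"))
  base <- fba(model, objective)
  if (base@status == "optimal" && base@objectiveValue >= minObjective)
    return(list(new("GapfillResult", added = character(0),
                    restoredObjective = base@objectiveValue)))
  if (!length(universal)) .err("empty universal pool", "noFillExistsError")
  poolIds <- vapply(universal, `[[`, character(1), "id")
  clash <- intersect(poolIds, model@reactions$id)
  if (length(clash))
    .err(paste0("pool reactions already in model: ",
                paste(clash, collapse = ", ")), "duplicateIdError")
  ext <- addReactions(model, universal, metabolites = metabolites)
  S <- as.matrix(ext@stoichiometry)
  lb <- ext@reactions$lower; ub <- ext@reactions$upper
  poolIdx <- match(poolIds, ext@reactions$id)
  objIdx <- match(objective, ext@reactions$id)
  cuts <- list()
  out <- list()
  minSize <- NA_real_
  repeat {
    sol <- .gapfillBnB(S, lb, ub, poolIdx, objIdx, minObjective, cuts)
    if (is.null(sol$selection)) break
    if (is.na(minSize)) minSize <- sol$size
    if (sol$size > minSize + 1e-6) break  # only minimal-cardinality sets
    added <- poolIds[sol$selection]
    restored <- fba(addReactions(model, universal[sol$selection],
                                 metabolites = metabolites), objective)
    if (restored@status != "optimal" ||
        restored@objectiveValue < minObjective - 1e-9)
      stop(errorCondition("gap-fill verification failed",
                          class = c("solverError", "acetofluxError")))
    out[[length(out) + 1L]] <- new("GapfillResult", added = added,
                                   restoredObjective = restored@objectiveValue)
    if (length(out) >= maxSolutions) break
    cuts[[length(cuts) + 1L]] <- sol$selection
  }
  if (!length(out))
    .err("no reaction set in the pool restores the objective",
         "noFillExistsError")
  out
}
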