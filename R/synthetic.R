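#' @include fba.R
NULL

#' Generate a random network with a planted LP optimum
#'
#' Builds \code{nPaths} parallel source-to-sink chains, each fed by an
#' exchange with a random uptake cap, all draining into a shared sink
#' exchange. The maximal sink flux is the sum of the caps by construction,
#' giving an analytically known optimum for engine validation. Generation is
#' reproducible per seed (the caller's RNG state is preserved).
#'
#' @param nPaths number of parallel chains (>= 1).
#' @param pathLength internal reactions per chain (>= 1).
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticNetwork}.
#' @examples
#' net <- randomFeasibleNetwork(2, 2, seed = 7)
#' net@plantedOptimum
#' @export
randomFeasibleNetwork <- function(nPaths, pathLength, seed = 0L) {
  if (nPaths < 1 || pathLength < 1)
    .err("nPaths and pathLength must be >= 1", "valueError")
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(seed)
  caps <- round(stats::runif(nPaths, 0.5, 10), 4)
  mets <- list(metabolite("z_e", compartment = "e"))
  rxns <- list()
  for (k in seq_len(nPaths)) {
    src <- sprintf("s%d_e", k)
    mets[[length(mets) + 1L]] <- metabolite(src, compartment = "e")
    rxns[[length(rxns) + 1L]] <-
      reaction(sprintf("EX_s%d", k), stats::setNames(-1, src), -caps[k], 0)
    prev <- src
    for (step in seq_len(pathLength)) {
      nxt <- if (step == pathLength) "z_e" else sprintf("a%d_%d_c", k, step)
      if (nxt != "z_e")
        mets[[length(mets) + 1L]] <- metabolite(nxt)
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("R%d_%d", k, step),
                 stats::setNames(c(-1, 1), c(prev, nxt)), 0, 1000)
      prev <- nxt
    }
  }
  rxns[[length(rxns) + 1L]] <- reaction("EX_z", c(z_e = -1), 0, 1000)
  model <- buildModel(do.call(rbind, mets), rxns, objective = "EX_z")
  new("SyntheticNetwork", model = model, plantedOptimum = sum(caps),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticNetwork", function(object) {
  cat(sprintf("SyntheticNetwork (seed %d): %d reactions, planted optimum %.4f\n",
              object@seed, nrow(object@model@reactions),
              object@plantedOptimum))
})

#' Brute-force LP oracle by vertex enumeration
#'
#' Independent check of the simplex engine: enumerates every candidate basic
#' feasible solution of \code{\{S v = 0, lb <= v <= ub\}} by assigning each
#' reaction to its lower bound, its upper bound, or the free (basic) set,
#' solving the free subsystem by least squares and keeping consistent,
#' in-bounds assignments. Exponential (3^n patterns) but exact at the small
#' scale it guards.
#'
#' @param model a \linkS4class{MetabolicModel} with at most 10 reactions and
#'   finite bounds.
#' @param objective reaction id to maximize (default model objective).
#' @return the optimal objective value.
#' @export
bruteForceLPOracle <- function(model, objective = NULL) {
  objective <- objective %||%
    (if (length(model@objective)) model@objective else
       .err("no objective", "referenceError"))
  S <- as.matrix(model@stoichiometry)
  n <- ncol(S)
  if (n > 10) .err("oracle limited to 10 reactions", "valueError")
  lb <- model@reactions$lower; ub <- model@reactions$upper
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    .err("oracle requires finite bounds", "unboundedError")
  cvec <- as.numeric(model@reactions$id == objective)
  best <- -Inf
  patterns <- expand.grid(rep(list(c(-1L, 0L, 1L)), n))
  for (r in seq_len(nrow(patterns))) {
    pat <- as.integer(patterns[r, ])
    v <- ifelse(pat == -1L, lb, ifelse(pat == 1L, ub, NA_real_))
    free <- which(pat == 0L)
    if (length(free) > nrow(S)) next   # cannot be a basic solution
    if (length(free)) {
      fixedIdx <- which(pat != 0L)
      rhs <- if (length(fixedIdx))
        -as.vector(S[, fixedIdx, drop = FALSE] %*% v[fixedIdx])
      else rep(0, nrow(S))
      Bm <- S[, free, drop = FALSE]
      qd <- qr(Bm)
      if (qd$rank < length(free)) next # rank-deficient free set
      v[free] <- qr.coef(qd, rhs)
    }
    if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
    if (max(abs(S %*% v)) > 1e-8) next
    best <- max(best, sum(cvec * v))
  }
  if (!is.finite(best))
    .err("no feasible basic solution found", "infeasibleScenario")
  best
}
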