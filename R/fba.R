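#' @include lp-solver.R
NULL

.asFluxSolution <- function(res) {
  if (res$status != "optimal")
    return(new("FluxSolution", status = res$status,
               objectiveValue = NA_real_, fluxes = numeric(0)))
  new("FluxSolution", status = "optimal", objectiveValue = res$objective,
      fluxes = res$x)
}

#' Constrain a model with a growth medium
#'
#' A medium is a named list (or data.frame with columns \code{id},
#' \code{lower}, \code{upper}) mapping exchange-reaction ids to flux bounds in
#' mmol/gDW/h. All exchanges not named in the medium are closed to uptake
#' (lower bound 0) while secretion stays open; named exchanges receive the
#' given bounds. Negative flux is uptake.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium named list of \code{c(lower, upper)} pairs, or an equivalent
#'   data.frame.
#' @return the constrained model.
#' @examples
#' \dontrun{applyMedium(model, list(EX_fru = c(-1.88, 0)))}
#' @export
applyMedium <- function(model, medium = list()) {
  ex <- exchangeReactions(model)
  if (is.data.frame(medium)) {
    nm <- medium$id
    medium <- stats::setNames(
      lapply(seq_len(nrow(medium)),
             function(i) c(medium$lower[i], medium$upper[i])), nm)
  }
  unknown <- setdiff(names(medium), ex)
  if (length(unknown))
    .err(paste0("medium names non-exchange or unknown reactions: ",
                paste(unknown, collapse = ", ")), "keyError")
  idx <- match(ex, model@reactions$id)
  model@reactions$lower[idx] <- pmax(model@reactions$lower[idx], 0)
  for (id in names(medium)) {
    bnd <- medium[[id]]
    if (bnd[1] > bnd[2]) .err("medium lower bound above upper", "boundsError")
    model <- setBounds(model, id, lower = bnd[1], upper = bnd[2])
  }
  model
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of the objective reaction subject to the
#' steady-state constraint S v = 0 and the flux bounds.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id to optimize; defaults to the model objective.
#' @param maximize direction (default maximize).
#' @return a \linkS4class{FluxSolution}; for the biomass objective the
#'   objective value is the specific growth rate in h^-1.
#' @export
fba <- function(model, objective = NULL, maximize = TRUE) {
  objective <- objective %||%
    (if (length(model@objective)) model@objective else
       .err("model has no objective reaction", "referenceError"))
  if (!objective %in% model@reactions$id)
    .err(paste0("unknown objective reaction: ", objective), "referenceError")
  res <- .modelLP(model, stats::setNames(1, objective), maximize = maximize)
  sol <- .asFluxSolution(res)
  if (sol@status == "optimal") {
    resid <- max(abs(as.vector(model@stoichiometry %*% sol@fluxes)), 0)
    if (resid > 1e-6)
      stop(errorCondition(sprintf("steady-state residual %.2e", resid),
                          class = c("solverError", "acetofluxError")))
  }
  sol
}

#' Flux variability analysis
#'
#' For each reaction, the minimal and maximal flux attainable while the
#' objective retains at least \code{fraction} of its optimum.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param fraction required fraction of the optimal objective (default 1).
#' @param reactions reaction ids to scan (default all).
#' @return data.frame with columns \code{id}, \code{min}, \code{max}.
#' @export
fva <- function(model, fraction = 1, reactions = NULL) {
  obj <- if (length(model@objective)) model@objective else
    .err("model has no objective reaction", "referenceError")
  base <- fba(model)
  if (base@status != "optimal")
    .err(paste0("base FBA not optimal: ", base@status), "infeasibleScenario")
  opt <- base@objectiveValue
  model <- setBounds(model, obj, lower = fraction * opt - 1e-9)
  ids <- reactions %||% model@reactions$id
  lo <- hi <- numeric(length(ids))
  for (k in seq_along(ids)) {
    cv <- stats::setNames(1, ids[k])
    lo[k] <- .modelLP(model, cv, maximize = FALSE)$objective
    hi[k] <- .modelLP(model, cv, maximize = TRUE)$objective
  }
  data.frame(id = ids, min = lo, max = hi, stringsAsFactors = FALSE)
}

#' Parsimonious flux balance analysis
#'
#' Among the alternate optima of [fba()], returns the flux vector minimizing
#' the total absolute flux (the classic pFBA selection), giving a unique,
#' audit-friendly solution in the scenarios of this package. Futile cycles
#' carry zero flux in the returned solution. The solve is deterministic for a
#' given model (fixed simplex pivoting order).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id; defaults to the model objective.
#' @return a \linkS4class{FluxSolution} whose \code{objectiveValue} is the
#'   (unchanged) optimal objective; attribute \code{totalFlux} holds the
#'   minimized sum of absolute fluxes.
#' @export
parsimoniousFBA <- function(model, objective = NULL) {
  objective <- objective %||%
    (if (length(model@objective)) model@objective else
       .err("model has no objective reaction", "referenceError"))
  base <- fba(model, objective)
  if (base@status != "optimal") return(base)
  opt <- base@objectiveValue
  rxn <- model@reactions
  j <- match(objective, rxn$id)
  rxn$lower[j] <- opt - 1e-9
  rxn$upper[j] <- min(rxn$upper[j], opt + 1e-9)
  S <- as.matrix(model@stoichiometry)
  n <- ncol(S)
  A <- cbind(S, -S)
  lbP <- pmax(rxn$lower, 0); ubP <- pmax(rxn$upper, 0)
  lbQ <- pmax(-rxn$upper, 0); ubQ <- pmax(-rxn$lower, 0)
  res <- solveLP(A, rep(0, nrow(S)), rep(1, 2 * n),
                 c(lbP, lbQ), c(ubP, ubQ), maximize = FALSE)
  if (res$status != "optimal")
    stop(errorCondition(paste0("pFBA solve failed: ", res$status),
                        class = c("solverError", "acetofluxError")))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- rxn$id
  v[abs(v) < 1e-10] <- 0
  sol <- new("FluxSolution", status = "optimal",
             objectiveValue = unname(v[objective]), fluxes = v)
  attr(sol, "totalFlux") <- res$objective
  sol
}

#' Single-gene deletion screen
#'
#' Knocks out each gene in turn (reactions whose GPR evaluates inactive get
#' zero bounds), re-runs FBA, and reports the growth ratio relative to the
#' wild type. A knockout that is infeasible or grows below 1e-9 h^-1 is
#' reported with growth ratio 0.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param genes genes to screen (default: all model genes).
#' @return data.frame with columns \code{gene}, \code{status}, \code{growth},
#'   \code{growthRatio}.
#' @export
singleGeneDeletion <- function(model, genes = NULL) {
  genes <- genes %||% model@genes
  wt <- fba(model)
  if (wt@status != "optimal")
    .err("wild-type FBA not optimal", "infeasibleScenario")
  wtG <- wt@objectiveValue
  rows <- lapply(genes, function(g) {
    ko <- knockoutGenes(model, g)
    sol <- fba(ko)
    growth <- if (sol@status == "optimal") sol@objectiveValue else 0
    if (growth < 1e-9) growth <- 0
    ratio <- if (wtG > 1e-9) growth / wtG else NA_real_
    data.frame(gene = g, status = sol@status, growth = growth,
               growthRatio = ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
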