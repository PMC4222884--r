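#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a compartmented stoichiometric network
#'
#' The central container of the package. Rows of the stoichiometric matrix are
#' metabolites, columns are reactions; negative coefficients denote
#' consumption. Reaction bounds are fluxes in mmol/gDW/h; an exchange reaction
#' touches exactly one metabolite, in the extracellular compartment, with the
#' convention that negative flux is uptake and positive flux is secretion.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula} (Hill string, "" for lumped species), \code{charge}
#'   (signed integer) and \code{compartment} (\code{"c"} cytosol or \code{"e"}
#'   extracellular).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower}, \code{upper} (mmol/gDW/h), \code{gpr} (boolean rule string,
#'   "" for none) and \code{subsystem}.
#' @slot stoichiometry sparse \code{dgCMatrix}, metabolites x reactions, with
#'   matching dimnames.
#' @slot genes character vector of gene ids.
#' @slot objective id of the objective reaction (biomass by convention), or
#'   \code{character(0)} for none.
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "dgCMatrix",
    genes = "character",
    objective = "character"
  )
)

.COMPARTMENTS <- c("c", "e")

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  needMet <- c("id", "name", "formula", "charge", "compartment")
  needRxn <- c("id", "name", "lower", "upper", "gpr", "subsystem")
  if (!all(needMet %in% names(met)))
    return("metabolite table lacks required columns")
  if (!all(needRxn %in% names(rxn)))
    return("reaction table lacks required columns")
  ids <- c(met$id, rxn$id, object@genes)
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate ids: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!all(met$compartment %in% .COMPARTMENTS))
    msg <- c(msg, "metabolite compartment outside declared set {c, e}")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msg <- c(msg, "stoichiometric matrix dimensions do not match tables")
  if (nrow(met) && !identical(rownames(S), met$id))
    msg <- c(msg, "matrix rownames do not match metabolite ids")
  if (nrow(rxn) && !identical(colnames(S), rxn$id))
    msg <- c(msg, "matrix colnames do not match reaction ids")
  if (any(rxn$lower > rxn$upper + 1e-12))
    msg <- c(msg, "reaction with lower bound above upper bound")
  if (length(object@objective) > 1L)
    msg <- c(msg, "objective must be a single reaction id")
  if (length(object@objective) == 1L && !(object@objective %in% rxn$id))
    msg <- c(msg, paste0("objective reaction not in model: ", object@objective))
  badGenes <- setdiff(unlist(lapply(rxn$gpr, gprGenes)), object@genes)
  if (length(badGenes))
    msg <- c(msg, paste0("GPR references unknown genes: ",
                         paste(badGenes, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FluxSolution: result of a flux balance analysis solve
#'
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @slot objectiveValue objective flux at the optimum (h^-1 for a biomass
#'   objective, mmol/gDW/h otherwise); \code{NA} unless optimal.
#' @slot fluxes named numeric vector of reaction fluxes (empty unless optimal).
#' @export
setClass("FluxSolution",
  representation(
    status = "character",
    objectiveValue = "numeric",
    fluxes = "numeric"
  )
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("unknown solver status")
  TRUE
})

#' CoreModelConfig: tunable parameters of the core reconstruction
#'
#' @slot hydrogenase cofactor specificity of the electron-bifurcating
#'   hydrogenase, \code{"NADP"} (default, following the genome evidence) or
#'   \code{"NAD"}.
#' @slot rnfProtonsPerFd protons translocated by the Rnf complex per reduced
#'   ferredoxin oxidized (default 2).
#' @slot atpsProtonsPerAtp protons consumed by the ATP synthase per ATP
#'   (default 4); together with the Rnf ratio this fixes 0.5 ATP per
#'   ferredoxin, the value implied by the published yield accounting.
#' @slot biomassAccoa,biomassAtp,biomassNadph,biomassNh4 lumped biomass drain
#'   coefficients in mmol per gDW.
#' @slot proteinFraction protein mass fraction of biomass (default 0.43);
#'   used to derive the default nitrogen demand.
#' @slot ngam non-growth-associated maintenance ATP flux (lower bound of the
#'   ATPM reaction, mmol/gDW/h; default 0).
#' @slot fructoseUptake default fructose uptake bound for the fructose medium
#'   presets (mmol/gDW/h, default 1.88).
#' @export
setClass("CoreModelConfig",
  representation(
    hydrogenase = "character",
    rnfProtonsPerFd = "numeric",
    atpsProtonsPerAtp = "numeric",
    biomassAccoa = "numeric",
    biomassAtp = "numeric",
    biomassNadph = "numeric",
    biomassNh4 = "numeric",
    proteinFraction = "numeric",
    ngam = "numeric",
    fructoseUptake = "numeric"
  )
)

setValidity("CoreModelConfig", function(object) {
  msg <- character()
  if (!object@hydrogenase %in% c("NADP", "NAD"))
    msg <- c(msg, "hydrogenase must be 'NADP' or 'NAD'")
  coefs <- c(object@biomassAccoa, object@biomassAtp, object@biomassNadph,
             object@biomassNh4, object@ngam, object@fructoseUptake)
  if (any(coefs < 0)) msg <- c(msg, "coefficients must be non-negative")
  if (object@rnfProtonsPerFd < 1 || object@atpsProtonsPerAtp < 1)
    msg <- c(msg, "proton stoichiometries must be at least 1")
  ## a two-electron carrier is worth at most one NAD(P)H; allowing more than
  ## 2 ATP-equivalents of pumping per ferredoxin would let the Rnf/ATPS loop
  ## mint free energy
  if (object@rnfProtonsPerFd >= object@atpsProtonsPerAtp * 2)
    msg <- c(msg, "rnfProtonsPerFd must be < 2 * atpsProtonsPerAtp")
  if (length(msg)) msg else TRUE
})

#' EquivalentLedger: reducing-equivalent bookkeeping for a product
#'
#' Net two-electron reducing equivalents (NADH, NADPH, reduced ferredoxin)
#' and substrate-level ATP consumed per unit product flux.
#'
#' @slot product product metabolite or drain id.
#' @slot view \code{"demand"} (carrier interconverters disabled; what the
#'   pathway itself consumes) or \code{"supply"} (interconverters active; how
#'   the electron donor provides the equivalents).
#' @slot nadh,nadph,fdx mol two-electron equivalents per mol product.
#' @slot atpSubstrateLevel mol ATP per mol product.
#' @export
setClass("EquivalentLedger",
  representation(
    product = "character",
    view = "character",
    nadh = "numeric",
    nadph = "numeric",
    fdx = "numeric",
    atpSubstrateLevel = "numeric"
  )
)

#' EnergyReport: chemiosmotic ATP accounting for a production scenario
#'
#' @slot translocatedProtonFlux protons translocated by Rnf per unit product
#'   flux (mmol/gDW/h at unit product).
#' @slot atpFromPmf translocated protons divided by the ATP synthase
#'   proton/ATP ratio.
#' @slot atpDeficit flux through the diagnostic ATP source needed to sustain
#'   the scenario (0 when the scenario is self-sufficient).
#' @slot atpSurplus maximal maintenance ATP flux once demand is met.
#' @slot feasibleForGrowth TRUE iff the deficit is zero.
#' @slot rnfFlux,hydrogenaseFlux fluxes of the Rnf complex and the
#'   bifurcating hydrogenase in the reported solution.
#' @export
setClass("EnergyReport",
  representation(
    translocatedProtonFlux = "numeric",
    atpFromPmf = "numeric",
    atpDeficit = "numeric",
    atpSurplus = "numeric",
    feasibleForGrowth = "logical",
    rnfFlux = "numeric",
    hydrogenaseFlux = "numeric"
  )
)

setValidity("EnergyReport", function(object) {
  if (object@atpDeficit > 1e-6 && object@atpSurplus > 1e-6)
    return("at most one of deficit and surplus may be positive")
  TRUE
})

#' SyntheticNetwork: a random network with a planted LP optimum
#'
#' @slot model the generated \linkS4class{MetabolicModel}.
#' @slot plantedOptimum true optimal objective value by construction.
#' @slot seed integer seed used for generation.
#' @export
setClass("SyntheticNetwork",
  representation(
    model = "MetabolicModel",
    plantedOptimum = "numeric",
    seed = "integer"
  )
)
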