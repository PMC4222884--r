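#' @include core-model.R
NULL

.PRODUCT_EXCHANGES <- c("EX_ac", "EX_etoh", "EX_lac", "EX_btd", "EX_for")

.productExchange <- function(product) {
  switch(product,
         accoa = "DM_accoa", acetate = "EX_ac", ac = "EX_ac",
         ethanol = "EX_etoh", etoh = "EX_etoh",
         .err(paste0("unknown product: ", product), "keyError"))
}

## Fix one product at unit flux and close every competing carbon/electron
## outlet (fermentation products and H2 evolution), leaving CO2 free.
.fixProduct <- function(model, product, flux = 1) {
  ex <- .productExchange(product)
  if (ex == "DM_accoa")
    model <- addReactions(model, list(
      reaction("DM_accoa", c(accoa_c = -1, coa_c = 1), 0, 1000,
               name = "acetyl-CoA drain (audit)", subsystem = "Biomass")))
  model <- setBounds(model, "BIOMASS", 0, 0)
  block <- setdiff(.PRODUCT_EXCHANGES, ex)
  model <- setBounds(model, block, 0, 0)
  j <- match("EX_h2", model@reactions$id)
  model <- setBounds(model, "EX_h2", upper = max(0, model@reactions$lower[j]))
  setBounds(model, ex, flux, flux)
}

#' Audit the reducing equivalents behind a product
#'
#' Quantifies the two-electron reducing equivalents (NADH, NADPH, reduced
#' ferredoxin) and substrate-level ATP behind one mole of product.
#'
#' In the \emph{demand} view (\code{interconverters = FALSE}) the carrier
#' interconversion machinery (Rnf, Nfn, hydrogenase, ATP synthase) and the
#' substrate-level routes are disabled and each carrier is fed by a dedicated
#' pseudo-supply; the minimal supply fluxes at unit product are the intrinsic
#' pathway demand. For acetyl-CoA from CO2 this is 1 NADPH, 1 ferredoxin,
#' 2 NADH and 1 ATP; ethanol adds 2 NADH.
#'
#' In the \emph{supply} view (\code{interconverters = TRUE}) the intact model
#' runs on the stated electron donor and the ledger tallies carrier
#' production by the donor-oxidizing reactions (CO dehydrogenase, bifurcating
#' hydrogenase) in the parsimonious solution: with CO as sole donor all six
#' ethanol equivalents arrive as reduced ferredoxin; with H2 they arrive
#' split according to the hydrogenase cofactor.
#'
#' @param model core model from [buildCoreModel()].
#' @param product \code{"accoa"}, \code{"ethanol"} or \code{"acetate"}.
#' @param carbonSource \code{"co2"} or \code{"co"}.
#' @param interconverters FALSE for the demand view (default), TRUE for the
#'   supply view.
#' @return an \linkS4class{EquivalentLedger}.
#' @export
reducingEquivalentAudit <- function(model, product,
                                    carbonSource = c("co2", "co"),
                                    interconverters = FALSE) {
  carbonSource <- match.arg(carbonSource)
  if (!interconverters) {
    med <- list(EX_h = c(-1000, 1000), EX_h2o = c(-1000, 1000),
                EX_pi = c(-1000, 1000))
    med[[if (carbonSource == "co2") "EX_co2" else "EX_co"]] <- c(-1000, 1000)
    m <- applyMedium(model, med)
    off <- intersect(c("RNF", "NFN", "HYD", "ATPS", "ATPM", "GLYC", "GLYCn"),
                     m@reactions$id)
    m <- setBounds(m, off, 0, 0)
    m <- addReactions(m, list(
      reaction("SUP_nadh", c(nad_c = -1, h_c = -1, nadh_c = 1), 0, 1000,
               name = "NADH pseudo-supply", subsystem = "Audit"),
      reaction("SUP_nadph", c(nadp_c = -1, h_c = -1, nadph_c = 1), 0, 1000,
               name = "NADPH pseudo-supply", subsystem = "Audit"),
      reaction("SUP_fdx", c(fdxo_c = -1, fdxr_c = 1), 0, 1000,
               name = "ferredoxin pseudo-supply", subsystem = "Audit"),
      reaction("SUP_atp", c(adp_c = -1, pi_c = -1, h_c = -1,
                            atp_c = 1, h2o_c = 1), 0, 1000,
               name = "ATP pseudo-supply", subsystem = "Audit"),
      reaction("VALVE_h", c(h_c = 1), -1000, 1000,
               name = "cytosolic proton valve (audit)", subsystem = "Audit")))
    m <- .fixProduct(m, product)
    res <- .modelLP(m, c(SUP_nadh = 1, SUP_nadph = 1, SUP_fdx = 1,
                         SUP_atp = 1), maximize = FALSE)
    if (res$status != "optimal")
      .err(paste0("product not reachable in audit: ", res$status),
           "infeasibleScenario")
    return(new("EquivalentLedger", product = product, view = "demand",
               nadh = unname(res$x["SUP_nadh"]),
               nadph = unname(res$x["SUP_nadph"]),
               fdx = unname(res$x["SUP_fdx"]),
               atpSubstrateLevel = unname(res$x["SUP_atp"])))
  }
  ## supply view: intact model on the donor medium; a diagnostic ATP source
  ## keeps ATP-deficient configurations well-defined (cf. energyGapAnalysis)
  cfg <- coreConfig(model)
  med <- mediumPreset(if (carbonSource == "co") "co" else "h2_co2", cfg)
  med$EX_nh4 <- NULL
  v <- .canonicalScenario(model, med, product)$fluxes
  codh <- if ("CODH" %in% names(v)) max(v[["CODH"]], 0) else 0
  hydF <- if ("HYD" %in% names(v)) max(v[["HYD"]], 0) else 0
  hydIsNadp <- cfg@hydrogenase == "NADP"
  atpSl <- 2 * max(v["GLYC"], 0) + max(v["ACKr"], 0)
  new("EquivalentLedger", product = product, view = "supply",
      nadh = if (hydIsNadp) 0 else hydF,
      nadph = if (hydIsNadp) hydF else 0,
      fdx = codh + hydF,
      atpSubstrateLevel = unname(atpSl))
}

#' @rdname accessors
#' @export
setMethod("totalEquivalents", "EquivalentLedger",
          function(x) x@nadh + x@nadph + x@fdx)

setMethod("show", "EquivalentLedger", function(object) {
  cat(sprintf("EquivalentLedger (%s view) per mol %s:\n",
              object@view, object@product))
  cat(sprintf("  NADH %.4g | NADPH %.4g | Fd %.4g | total %.4g equivalents; substrate-level ATP %.4g\n",
              object@nadh, object@nadph, object@fdx,
              totalEquivalents(object), object@atpSubstrateLevel))
})

## Canonical flux distribution of a fixed-product scenario: medium applied,
## knockouts in place, biomass and competing products blocked, diagnostic
## cytosolic ATP source added and minimized, then a parsimonious solve with
## the diagnostic pinned at its minimum.
.canonicalScenario <- function(model, medium, product,
                               knockouts = character()) {
  m <- applyMedium(model, medium)
  if (length(knockouts)) m <- knockoutGenes(m, knockouts)
  m <- .fixProduct(m, product)
  m <- addReactions(m, list(
    reaction("DIAG_ATP", c(adp_c = -1, pi_c = -1, h_c = -1,
                           atp_c = 1, h2o_c = 1), 0, 1000,
             name = "diagnostic ATP source", subsystem = "Audit")))
  res <- .modelLP(m, c(DIAG_ATP = 1), maximize = FALSE)
  if (res$status != "optimal")
    .err(paste0("product unreachable even with diagnostic ATP: ", res$status),
         "infeasibleScenario")
  deficit <- max(res$objective, 0)
  if (deficit < 1e-9) deficit <- 0
  m2 <- setBounds(m, "DIAG_ATP", deficit, deficit)
  objectiveReaction(m2) <- .productExchange(product)
  sol <- parsimoniousFBA(m2)
  list(fluxes = fluxes(sol), deficit = deficit, model = m)
}

#' Chemiosmotic ATP accounting for a production scenario
#'
#' Reproduces the ATP bookkeeping at the Rnf/ATP-synthase couple for a fixed
#' product flux of 1 mmol/gDW/h: applies the medium and gene knockouts,
#' blocks biomass and competing products, adds a diagnostic cytosolic ATP
#' source, and minimizes its flux. The minimized diagnostic flux is the ATP
#' deficit of the scenario (0 when it is self-sufficient); the parsimonious
#' flux distribution at that deficit yields the Rnf proton translocation
#' rate, from which the chemiosmotic ATP yield is
#' \code{translocated / atpsProtonsPerAtp}. When the deficit is zero, the
#' surplus is the maximal maintenance ATPase flux with the diagnostic
#' removed.
#'
#' @param model core model from [buildCoreModel()].
#' @param medium medium list, e.g. \code{mediumPreset("h2_co2")}.
#' @param product \code{"ethanol"}, \code{"acetate"} or \code{"accoa"}.
#' @param knockouts gene ids to delete (e.g. \code{"ackA"}).
#' @return an \linkS4class{EnergyReport}.
#' @examples
#' \dontrun{
#' energyGapAnalysis(buildCoreModel(), mediumPreset("h2_co2"),
#'                   "ethanol", "ackA")
#' }
#' @export
energyGapAnalysis <- function(model, medium, product, knockouts = character()) {
  cfg <- coreConfig(model)
  can <- .canonicalScenario(model, medium, product, knockouts)
  deficit <- can$deficit
  m <- can$model
  v <- can$fluxes
  rnf <- unname(v["RNF"])
  hydF <- if ("HYD" %in% names(v)) unname(v["HYD"]) else 0
  transloc <- cfg@rnfProtonsPerFd * rnf
  surplus <- 0
  if (deficit == 0) {
    m3 <- setBounds(m, "DIAG_ATP", 0, 0)
    sres <- .modelLP(m3, c(ATPM = 1), maximize = TRUE)
    if (sres$status == "optimal") surplus <- max(sres$objective, 0)
  }
  new("EnergyReport",
      translocatedProtonFlux = transloc,
      atpFromPmf = transloc / cfg@atpsProtonsPerAtp,
      atpDeficit = deficit,
      atpSurplus = if (surplus < 1e-9) 0 else surplus,
      feasibleForGrowth = deficit == 0,
      rnfFlux = rnf, hydrogenaseFlux = hydF)
}

setMethod("show", "EnergyReport", function(object) {
  cat("EnergyReport:\n")
  cat(sprintf("  Rnf flux %.4g -> %.4g translocated H+ -> %.4g ATP at the synthase\n",
              object@rnfFlux, object@translocatedProtonFlux,
              object@atpFromPmf))
  cat(sprintf("  ATP deficit %.4g | surplus %.4g | feasible for growth: %s\n",
              object@atpDeficit, object@atpSurplus,
              object@feasibleForGrowth))
})

#' Acetate-kinase knockout feasibility panel
#'
#' Screens the acetate-kinase deletion across hydrogenase configurations and
#' growth media, reporting wild-type and knockout growth, feasibility and
#' the dominant secreted product. Reproduces the published pattern: the
#' knockout grows on fructose and on CO under either hydrogenase, and on
#' H2/CO2 only when the bifurcating hydrogenase is NADP-specific.
#'
#' @param configs hydrogenase cofactors to test (default both).
#' @param media medium preset names (default fructose, co, h2_co2).
#' @param gene knocked-out gene (default \code{"ackA"}).
#' @return data.frame with one row per config x medium.
#' @export
ackaPanel <- function(configs = c("NADP", "NAD"),
                      media = c("fructose", "co", "h2_co2"),
                      gene = "ackA") {
  rows <- list()
  for (cof in configs) {
    cfg <- coreModelConfig(hydrogenase = cof)
    model <- buildCoreModel(cfg)
    for (med in media) {
      m <- applyMedium(model, mediumPreset(med, cfg))
      wt <- fba(m)
      wtG <- if (wt@status == "optimal") wt@objectiveValue else 0
      ko <- knockoutGenes(m, gene)
      koSol <- fba(ko)
      koG <- if (koSol@status == "optimal") koSol@objectiveValue else 0
      if (koG < 1e-9) koG <- 0
      dom <- function(mm, g) {
        if (g < 1e-9) return(NA_character_)
        v <- fluxes(parsimoniousFBA(mm))
        prods <- c(acetate = "EX_ac", ethanol = "EX_etoh",
                   lactate = "EX_lac", butanediol = "EX_btd")
        sec <- vapply(prods, function(id) max(v[[id]], 0), numeric(1))
        if (max(sec) < 1e-9) "none" else names(which.max(sec))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hydrogenase = cof, medium = med,
        wildtypeGrowth = wtG, knockoutGrowth = koG,
        feasible = koG > 0,
        wildtypeProduct = dom(m, wtG), knockoutProduct = dom(ko, koG),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Nitrate versus ammonium nitrogen-source scenario
#'
#' Compares growth on fructose with ammonium against ammonium-free medium
#' with nitrate as sole nitrogen source, at equal fructose uptake and
#' maximal growth. Reports the acetate fluxes, their relative change
#' (negative: nitrate reduction diverts electrons from CO2 refixation into
#' acetate), and the nitrogen mass balance, which closes stoichiometrically:
#' nitrate consumed equals ammonium secreted plus nitrogen drained into
#' biomass.
#'
#' @param model core model from [buildCoreModel()].
#' @param fructoseUptake uptake bound in mmol/gDW/h (default from config).
#' @return list with acetate fluxes, relative change, growth rates and the
#'   nitrogen balance components.
#' @export
nitrateScenario <- function(model, fructoseUptake = NULL) {
  cfg <- coreConfig(model)
  up <- fructoseUptake %||% cfg@fructoseUptake
  solN <- parsimoniousFBA(applyMedium(model,
    mediumPreset("fructose", cfg, uptake = up)))
  solX <- parsimoniousFBA(applyMedium(model,
    mediumPreset("fructose_nitrate", cfg, uptake = up)))
  if (solN@status != "optimal" || solX@status != "optimal")
    .err("nitrate scenario media infeasible", "infeasibleScenario")
  vN <- fluxes(solN); vX <- fluxes(solX)
  acNh4 <- max(vN[["EX_ac"]], 0)
  acNo3 <- max(vX[["EX_ac"]], 0)
  biomassN <- cfg@biomassNh4 * solX@objectiveValue
  list(
    acetateFluxNh4 = acNh4,
    acetateFluxNo3 = acNo3,
    relativeChange = (acNo3 - acNh4) / acNh4,
    growthNh4 = solN@objectiveValue,
    growthNo3 = solX@objectiveValue,
    no3Consumption = max(-vX[["EX_no3"]], 0),
    nh4Secretion = max(vX[["EX_nh4"]], 0),
    biomassNitrogen = biomassN
  )
}

#' Substrate growth screen
#'
#' Growth rate and acetate production per substrate at a fixed uptake bound,
#' the qualitative counterpart of the published substrate table (on the core
#' model formate supports the slowest growth).
#'
#' @param model core model from [buildCoreModel()].
#' @param substrates subset of \code{c("fructose", "pyruvate", "formate",
#'   "h2_co2", "co")}; unknown entries are skipped with a warning.
#' @param uptake uptake bound applied to the organic substrates
#'   (default 5 mmol/gDW/h); the gas media keep their standard caps
#'   (CO2 10 with H2 20, CO 20).
#' @return data.frame with columns \code{substrate}, \code{growth},
#'   \code{acetate}.
#' @export
substrateGrowthScreen <- function(model,
                                  substrates = c("fructose", "pyruvate",
                                                 "formate", "h2_co2", "co"),
                                  uptake = 5) {
  cfg <- coreConfig(model)
  rows <- list()
  for (s in substrates) {
    up <- if (s %in% c("h2_co2", "co")) NULL else uptake
    med <- tryCatch(mediumPreset(s, cfg, uptake = up),
                    error = function(e) NULL)
    if (is.null(med)) {
      warning("unknown substrate skipped: ", s, call. = FALSE)
      next
    }
    sol <- tryCatch(parsimoniousFBA(applyMedium(model, med)),
                    error = function(e) NULL)
    growth <- 0; acet <- 0
    if (!is.null(sol) && sol@status == "optimal" &&
        sol@objectiveValue > 1e-9) {
      growth <- sol@objectiveValue
      acet <- max(fluxes(sol)[["EX_ac"]], 0)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      substrate = s, growth = growth, acetate = acet,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
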