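#' @include fba.R
NULL

#' Configuration of the core acetogen reconstruction
#'
#' Collects the tunable stoichiometric parameters of the core model: the
#' cofactor specificity of the electron-bifurcating hydrogenase, the Rnf and
#' ATP synthase proton stoichiometries (their ratio fixes the ATP yield per
#' ferredoxin oxidized at the membrane; defaults 2 and 4 give 0.5), the
#' lumped biomass drain coefficients and the maintenance demand.
#'
#' @param hydrogenase \code{"NADP"} (default) or \code{"NAD"}.
#' @param rnfProtonsPerFd protons translocated per ferredoxin at Rnf
#'   (default 2).
#' @param atpsProtonsPerAtp protons per ATP at the synthase (default 4).
#' @param biomassAccoa,biomassAtp,biomassNadph biomass drain coefficients in
#'   mmol per gDW (defaults 20, 40, 10).
#' @param biomassNh4 nitrogen demand in mmol NH4 per gDW; default derived
#'   from the protein fraction (protein is 16\% nitrogen by mass).
#' @param proteinFraction protein mass fraction of biomass (default 0.43).
#' @param ngam non-growth-associated maintenance in mmol ATP/gDW/h
#'   (default 0).
#' @param fructoseUptake fructose uptake bound used by the fructose medium
#'   presets (default 1.88 mmol/gDW/h, the experimentally constrained rate).
#' @return a validated \linkS4class{CoreModelConfig}.
#' @export
coreModelConfig <- function(hydrogenase = c("NADP", "NAD"),
                            rnfProtonsPerFd = 2,
                            atpsProtonsPerAtp = 4,
                            biomassAccoa = 20,
                            biomassAtp = 40,
                            biomassNadph = 10,
                            biomassNh4 = NULL,
                            proteinFraction = 0.43,
                            ngam = 0,
                            fructoseUptake = 1.88) {
  hydrogenase <- match.arg(hydrogenase)
  biomassNh4 <- biomassNh4 %||% round(1000 * proteinFraction * 0.16 / 14, 2)
  tryCatch(
    new("CoreModelConfig", hydrogenase = hydrogenase,
        rnfProtonsPerFd = rnfProtonsPerFd,
        atpsProtonsPerAtp = atpsProtonsPerAtp,
        biomassAccoa = biomassAccoa, biomassAtp = biomassAtp,
        biomassNadph = biomassNadph, biomassNh4 = biomassNh4,
        proteinFraction = proteinFraction, ngam = ngam,
        fructoseUptake = fructoseUptake),
    error = function(e)
      .err(paste0("invalid core model configuration: ",
                  conditionMessage(e)), "configError"))
}

.coreMetabolites <- function() {
  cyt <- list(
    c("fru_c", "D-fructose", "C6H12O6", 0),
    c("pyr_c", "pyruvate", "C3H3O3", -1),
    c("accoa_c", "acetyl-CoA", "C23H34N7O17P3S", -4),
    c("coa_c", "coenzyme A", "C21H32N7O16P3S", -4),
    c("atp_c", "ATP", "C10H12N5O13P3", -4),
    c("adp_c", "ADP", "C10H12N5O10P2", -3),
    c("pi_c", "phosphate", "HO4P", -2),
    c("h_c", "proton", "H", 1),
    c("h2o_c", "water", "H2O", 0),
    c("nad_c", "NAD+", "C21H26N7O14P2", -1),
    c("nadh_c", "NADH", "C21H27N7O14P2", -2),
    c("nadp_c", "NADP+", "C21H25N7O17P3", -3),
    c("nadph_c", "NADPH", "C21H26N7O17P3", -4),
    c("co2_c", "CO2", "CO2", 0),
    c("co_c", "carbon monoxide", "CO", 0),
    c("h2_c", "hydrogen", "H2", 0),
    c("for_c", "formate", "CHO2", -1),
    c("thf_c", "tetrahydrofolate", "C19H21N7O6", -2),
    c("10fthf_c", "10-formyl-THF", "C20H21N7O7", -2),
    c("methf_c", "5,10-methenyl-THF", "C20H20N7O6", -1),
    c("mlthf_c", "5,10-methylene-THF", "C20H21N7O6", -2),
    c("5mthf_c", "5-methyl-THF", "C20H24N7O6", -1),
    c("cfesp_c", "corrinoid iron-sulfur protein", "Fe4S4", 0),
    c("mecfesp_c", "methyl-corrinoid iron-sulfur protein", "CH3Fe4S4", 1),
    c("fdxo_c", "oxidized ferredoxin", "Fe2S2", 0),
    c("fdxr_c", "reduced ferredoxin (2 e-)", "Fe2S2", -2),
    c("ac_c", "acetate", "C2H3O2", -1),
    c("actp_c", "acetyl phosphate", "C2H3O5P", -2),
    c("acald_c", "acetaldehyde", "C2H4O", 0),
    c("etoh_c", "ethanol", "C2H6O", 0),
    c("lac_c", "D-lactate", "C3H5O3", -1),
    c("btd_c", "2,3-butanediol", "C4H10O2", 0),
    c("no3_c", "nitrate", "NO3", -1),
    c("no2_c", "nitrite", "NO2", -1),
    c("ham_c", "hydroxylamine", "H3NO", 0),
    c("nh4_c", "ammonium", "H4N", 1)
  )
  extIds <- c("fru", "pyr", "for", "h2", "co2", "co", "ac", "etoh", "lac",
              "btd", "no3", "no2", "nh4", "h", "h2o", "pi")
  rows <- lapply(cyt, function(x)
    metabolite(x[1], x[2], x[3], as.integer(x[4]), "c"))
  cytTab <- do.call(rbind, rows)
  extTab <- do.call(rbind, lapply(extIds, function(id) {
    src <- cytTab[cytTab$id == paste0(id, "_c"), ]
    metabolite(paste0(id, "_e"), src$name, src$formula, src$charge, "e")
  }))
  rbind(cytTab, extTab)
}

#' Build the core model of C. ljungdahlii acetogenic metabolism
#'
#' Constructs the executable core reconstruction: lumped glycolysis (classic
#' EMP and a GAPN-type NADPH-yielding variant), pyruvate:ferredoxin
#' oxidoreductase, the Wood-Ljungdahl pathway (ferredoxin-dependent formate
#' dehydrogenase, formate-THF ligase, cyclohydrolase, NADP-dependent
#' methylene-THF dehydrogenase, electron-bifurcating methylene-THF reductase,
#' methyltransferase and the net CODH/ACS reaction), CO oxidation, acetate,
#' ethanol, lactate and 2,3-butanediol branches, the Rnf complex, ATP
#' synthase, the electron-bifurcating hydrogenase (NADP- or NAD-specific per
#' config), the Nfn transhydrogenase, the nitrate reduction pathway
#' (NTRARf/NTRIR5/HAMR with proton-symport transporters), a 4-component
#' lumped biomass drain, maintenance ATPase and exchanges. Every
#' non-exchange, non-biomass reaction is exactly elementally and charge
#' balanced.
#'
#' @param config a \linkS4class{CoreModelConfig} (default
#'   \code{coreModelConfig()}).
#' @return a \linkS4class{MetabolicModel} with objective \code{BIOMASS}.
#' @examples
#' model <- buildCoreModel()
#' fba(applyMedium(model, mediumPreset("h2_co2")))
#' @export
buildCoreModel <- function(config = coreModelConfig()) {
  if (!methods::is(config, "CoreModelConfig"))
    .err("config must be a CoreModelConfig", "configError")
  ok <- methods::validObject(config, test = TRUE)
  if (!isTRUE(ok))
    .err(paste0("invalid core model configuration: ",
                paste(ok, collapse = "; ")), "configError")
  p <- config@rnfProtonsPerFd
  q <- config@atpsProtonsPerAtp
  hyd <- if (config@hydrogenase == "NADP")
    reaction("HYD", c(h2_c = -2, fdxo_c = -1, nadp_c = -1,
                      fdxr_c = 1, nadph_c = 1, h_c = 3),
             -1000, 1000, gpr = "hydA and hydB and hydC",
             name = "electron-bifurcating hydrogenase (NADP)",
             subsystem = "Energy conservation")
  else
    reaction("HYD", c(h2_c = -2, fdxo_c = -1, nad_c = -1,
                      fdxr_c = 1, nadh_c = 1, h_c = 3),
             -1000, 1000, gpr = "hydA and hydB and hydC",
             name = "electron-bifurcating hydrogenase (NAD)",
             subsystem = "Energy conservation")
  bm <- c(accoa_c = -config@biomassAccoa, atp_c = -config@biomassAtp,
          h2o_c = -config@biomassAtp, nadph_c = -config@biomassNadph,
          nh4_c = -config@biomassNh4,
          coa_c = config@biomassAccoa, adp_c = config@biomassAtp,
          pi_c = config@biomassAtp, nadp_c = config@biomassNadph,
          h_c = config@biomassAtp)
  rxns <- list(
    ## central carbon
    reaction("GLYC", c(fru_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
                       pyr_c = 2, atp_c = 2, nadh_c = 2, h_c = 2, h2o_c = 2),
             0, 1000, gpr = "glyEMP",
             name = "glycolysis (lumped EMP)", subsystem = "Glycolysis"),
    reaction("GLYCn", c(fru_c = -1, nadp_c = -2,
                        pyr_c = 2, nadph_c = 2, h_c = 4),
             0, 1000, gpr = "gapN",
             name = "glycolysis via non-phosphorylating NADP-GAPDH (lumped)",
             subsystem = "Glycolysis"),
    reaction("PFOR", c(pyr_c = -1, coa_c = -1, fdxo_c = -1,
                       accoa_c = 1, co2_c = 1, fdxr_c = 1, h_c = 1),
             0, 1000, gpr = "nifJ",
             name = "pyruvate:ferredoxin oxidoreductase",
             subsystem = "Central metabolism"),
    ## Wood-Ljungdahl pathway, methyl (eastern) branch
    reaction("FDH7", c(co2_c = -1, fdxr_c = -1, h_c = -1,
                       for_c = 1, fdxo_c = 1),
             -1000, 1000, gpr = "fdhA",
             name = "formate dehydrogenase (ferredoxin)",
             subsystem = "Wood-Ljungdahl pathway"),
    reaction("FTHFLi", c(for_c = -1, thf_c = -1, atp_c = -1,
                         `10fthf_c` = 1, adp_c = 1, pi_c = 1),
             0, 1000, gpr = "fhs",
             name = "formate-tetrahydrofolate ligase",
             subsystem = "Wood-Ljungdahl pathway"),
    reaction("MTHFC", c(`10fthf_c` = -1, h_c = -1, methf_c = 1, h2o_c = 1),
             -1000, 1000, gpr = "fchA",
             name = "methenyl-THF cyclohydrolase",
             subsystem = "Wood-Ljungdahl pathway"),
    reaction("MTHFD", c(methf_c = -1, nadph_c = -1, mlthf_c = 1, nadp_c = 1),
             -1000, 1000, gpr = "CLJU_c37630",
             name = "methylene-THF dehydrogenase (NADP)",
             subsystem = "Wood-Ljungdahl pathway"),
    reaction("MTHFR5", c(mlthf_c = -1, nadh_c = -2, fdxo_c = -1, h_c = -1,
                         `5mthf_c` = 1, nad_c = 2, fdxr_c = 1),
             0, 1000, gpr = "CLJU_c37610 and CLJU_c37620",
             name = "methylene-THF reductase (electron bifurcating)",
             subsystem = "Wood-Ljungdahl pathway"),
    reaction("METR", c(`5mthf_c` = -1, cfesp_c = -1,
                       thf_c = 1, mecfesp_c = 1),
             0, 1000, gpr = "acsE",
             name = "methyl-THF:corrinoid methyltransferase",
             subsystem = "Wood-Ljungdahl pathway"),
    ## carbonyl (western) branch: net CODH/ACS
    reaction("CODH_ACS", c(mecfesp_c = -1, co2_c = -1, fdxr_c = -1,
                           coa_c = -1, h_c = -1,
                           accoa_c = 1, cfesp_c = 1, fdxo_c = 1, h2o_c = 1),
             0, 1000, gpr = "acsA and acsB",
             name = "CODH/acetyl-CoA synthase (net)",
             subsystem = "Wood-Ljungdahl pathway"),
    reaction("CODH", c(co_c = -1, h2o_c = -1, fdxo_c = -1,
                       co2_c = 1, fdxr_c = 1, h_c = 2),
             0, 1000, gpr = "CLJU_c09090 and CLJU_c09100 and CLJU_c09110",
             name = "carbon monoxide dehydrogenase (CO oxidation)",
             subsystem = "Wood-Ljungdahl pathway"),
    ## fermentation branches
    reaction("PTAr", c(accoa_c = -1, pi_c = -1, actp_c = 1, coa_c = 1),
             -1000, 1000, gpr = "pta", name = "phosphotransacetylase",
             subsystem = "Fermentation"),
    reaction("ACKr", c(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
             -1000, 1000, gpr = "ackA", name = "acetate kinase",
             subsystem = "Fermentation"),
    reaction("ACALD", c(accoa_c = -1, nadh_c = -1, h_c = -1,
                        acald_c = 1, coa_c = 1, nad_c = 1),
             -1000, 1000, gpr = "adhE1",
             name = "acetaldehyde dehydrogenase", subsystem = "Fermentation"),
    reaction("ALCD2x", c(acald_c = -1, nadh_c = -1, h_c = -1,
                         etoh_c = 1, nad_c = 1),
             -1000, 1000, gpr = "adhE2", name = "ethanol dehydrogenase",
             subsystem = "Fermentation"),
    reaction("LDH_D", c(pyr_c = -1, nadh_c = -1, h_c = -1,
                        lac_c = 1, nad_c = 1),
             -1000, 1000, gpr = "ldh", name = "D-lactate dehydrogenase",
             subsystem = "Fermentation"),
    reaction("BTD", c(pyr_c = -2, nadh_c = -1, h_c = -3,
                      btd_c = 1, co2_c = 2, nad_c = 1),
             0, 1000, gpr = "budA and budB",
             name = "2,3-butanediol synthesis (lumped)",
             subsystem = "Fermentation"),
    ## energy conservation
    reaction("RNF", stats::setNames(
               c(-1, -1, -(p + 1), 1, 1, p),
               c("fdxr_c", "nad_c", "h_c", "fdxo_c", "nadh_c", "h_e")),
             -1000, 1000, gpr = "rnfC and rnfD and rnfG",
             name = "Rnf complex (proton-translocating Fd:NAD+ oxidoreductase)",
             subsystem = "Energy conservation"),
    reaction("ATPS", stats::setNames(
               c(-1, -1, -q, 1, 1, q - 1),
               c("adp_c", "pi_c", "h_e", "atp_c", "h2o_c", "h_c")),
             -1000, 1000, gpr = "atpE", name = "ATP synthase",
             subsystem = "Energy conservation"),
    hyd,
    reaction("NFN", c(fdxr_c = -1, nadh_c = -1, nadp_c = -2, h_c = -1,
                      fdxo_c = 1, nad_c = 1, nadph_c = 2),
             -1000, 1000, gpr = "CLJU_c37240",
             name = "Nfn electron-bifurcating transhydrogenase",
             subsystem = "Energy conservation"),
    ## nitrate reduction pathway
    reaction("NTRARf", c(no3_c = -1, nadh_c = -1, h_c = -1,
                         no2_c = 1, nad_c = 1, h2o_c = 1),
             0, 1000, gpr = "narA", name = "nitrate reductase (soluble)",
             subsystem = "Nitrogen metabolism"),
    reaction("NTRIR5", c(no2_c = -1, nadh_c = -2, h_c = -3,
                         ham_c = 1, nad_c = 2, h2o_c = 1),
             0, 1000, gpr = "nirB", name = "nitrite reductase",
             subsystem = "Nitrogen metabolism"),
    reaction("HAMR", c(ham_c = -1, nadh_c = -1, h_c = -2,
                       nh4_c = 1, nad_c = 1, h2o_c = 1),
             0, 1000, gpr = "hcp", name = "hydroxylamine reductase",
             subsystem = "Nitrogen metabolism"),
    ## transport
    reaction("FRUt", c(fru_e = -1, fru_c = 1), 0, 1000, gpr = "fruPTS",
             name = "fructose uptake (lumped)", subsystem = "Transport"),
    reaction("PYRt2r", c(pyr_e = -1, h_e = -1, pyr_c = 1, h_c = 1),
             -1000, 1000, gpr = "pyrT",
             name = "pyruvate proton symport", subsystem = "Transport"),
    reaction("FORt", c(for_e = -1, for_c = 1), -1000, 1000, gpr = "focA",
             name = "formate transport", subsystem = "Transport"),
    reaction("H2t", c(h2_e = -1, h2_c = 1), -1000, 1000,
             name = "hydrogen diffusion", subsystem = "Transport"),
    reaction("CO2t", c(co2_e = -1, co2_c = 1), -1000, 1000,
             name = "CO2 diffusion", subsystem = "Transport"),
    reaction("COt", c(co_e = -1, co_c = 1), -1000, 1000,
             name = "CO diffusion", subsystem = "Transport"),
    reaction("ACt2r", c(ac_e = -1, h_e = -1, ac_c = 1, h_c = 1),
             -1000, 1000, gpr = "actP",
             name = "acetate proton symport", subsystem = "Transport"),
    reaction("ETOHt", c(etoh_e = -1, etoh_c = 1), -1000, 1000,
             name = "ethanol diffusion", subsystem = "Transport"),
    reaction("LACt2r", c(lac_e = -1, h_e = -1, lac_c = 1, h_c = 1),
             -1000, 1000, gpr = "lctP",
             name = "lactate proton symport", subsystem = "Transport"),
    reaction("BTDt", c(btd_e = -1, btd_c = 1), -1000, 1000,
             name = "2,3-butanediol diffusion", subsystem = "Transport"),
    reaction("NO3t2", c(no3_e = -1, h_e = -1, no3_c = 1, h_c = 1),
             0, 1000, gpr = "narT",
             name = "nitrate proton symport", subsystem = "Transport"),
    reaction("NO2t2r", c(no2_e = -1, h_e = -1, no2_c = 1, h_c = 1),
             -1000, 1000, gpr = "nirC",
             name = "nitrite proton symport", subsystem = "Transport"),
    reaction("NH4t", c(nh4_e = -1, nh4_c = 1), -1000, 1000, gpr = "amt",
             name = "ammonium transport", subsystem = "Transport"),
    reaction("PIt", c(pi_e = -1, pi_c = 1), -1000, 1000,
             name = "phosphate transport", subsystem = "Transport"),
    reaction("H2Ot", c(h2o_e = -1, h2o_c = 1), -1000, 1000,
             name = "water diffusion", subsystem = "Transport"),
    ## biomass and maintenance
    reaction("BIOMASS", bm, 0, 1000, name = "biomass drain (lumped)",
             subsystem = "Biomass"),
    reaction("ATPM", c(atp_c = -1, h2o_c = -1,
                       adp_c = 1, pi_c = 1, h_c = 1),
             config@ngam, 1000, name = "maintenance ATPase",
             subsystem = "Maintenance")
  )
  exMet <- c("fru", "pyr", "for", "h2", "co2", "co", "ac", "etoh", "lac",
             "btd", "no3", "no2", "nh4", "h", "h2o", "pi")
  mineral <- c("h", "h2o", "pi")
  exRxns <- lapply(exMet, function(id) {
    lo <- if (id %in% mineral) -1000 else 0
    reaction(paste0("EX_", id),
             stats::setNames(-1, paste0(id, "_e")), lo, 1000,
             name = paste0(id, " exchange"), subsystem = "Exchange")
  })
  model <- buildModel(.coreMetabolites(), c(rxns, exRxns),
                      objective = "BIOMASS")
  attr(model, "config") <- config
  model
}

#' Medium presets for the core model
#'
#' Returns the exchange-bound set for a growth condition, to be applied with
#' [applyMedium()]. Mineral species (protons, water, phosphate) are freely
#' exchanged in every preset. Available presets: \code{fructose}
#' (heterotrophic, ammonium nitrogen), \code{fructose_nitrate} (ammonium-free,
#' nitrate as sole nitrogen source), \code{h2_co2} (autotrophic, CO2 uptake
#' up to 10 and H2 up to 20 mmol/gDW/h), \code{co} (autotrophic, CO up to 20,
#' H2 closed), plus \code{pyruvate} and \code{formate} heterotrophic media.
#'
#' @param name preset name.
#' @param config a \linkS4class{CoreModelConfig}; sets the fructose uptake
#'   bound.
#' @param uptake optional override of the limiting substrate uptake bound
#'   (positive number, mmol/gDW/h).
#' @return named list of \code{c(lower, upper)} exchange bounds.
#' @export
mediumPreset <- function(name, config = coreModelConfig(), uptake = NULL) {
  minerals <- list(EX_h = c(-1000, 1000), EX_h2o = c(-1000, 1000),
                   EX_pi = c(-1000, 1000))
  nh4 <- list(EX_nh4 = c(-10, 1000))
  known <- c("fructose", "fructose_nitrate", "h2_co2", "co",
             "pyruvate", "formate")
  if (!name %in% known)
    .err(paste0("unknown medium preset: ", name), "keyError")
  fru <- uptake %||% config@fructoseUptake
  switch(name,
    fructose = c(minerals, nh4, list(EX_fru = c(-fru, 0))),
    fructose_nitrate = c(minerals,
                         list(EX_fru = c(-fru, 0), EX_no3 = c(-10, 1000))),
    h2_co2 = c(minerals, nh4, list(EX_co2 = c(-10, 1000),
                                   EX_h2 = c(-(uptake %||% 20), 1000))),
    co = c(minerals, nh4, list(EX_co = c(-(uptake %||% 20), 1000))),
    pyruvate = c(minerals, nh4, list(EX_pyr = c(-(uptake %||% 10), 0))),
    formate = c(minerals, nh4, list(EX_for = c(-(uptake %||% 10), 1000)))
  )
}

#' Configuration attached to a core model
#'
#' @param model a model produced by [buildCoreModel()].
#' @return the \linkS4class{CoreModelConfig} used to build it.
#' @export
coreConfig <- function(model) {
  cfg <- attr(model, "config")
  if (is.null(cfg)) .err("model carries no core configuration", "configError")
  cfg
}
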