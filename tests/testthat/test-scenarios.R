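core <- buildCoreModel()
coreNAD <- buildCoreModel(coreModelConfig(hydrogenase = "NAD"))

test_that("reducing-equivalent demand: 4 equivalents per acetyl-CoA, 6 per ethanol", {
  acc <- reducingEquivalentAudit(core, "accoa")
  expect_equal(acc@nadph, 1, tolerance = 1e-9)
  expect_equal(acc@fdx, 1, tolerance = 1e-9)
  expect_equal(acc@nadh, 2, tolerance = 1e-9)
  expect_equal(acc@atpSubstrateLevel, 1, tolerance = 1e-9)
  expect_equal(totalEquivalents(acc), 4, tolerance = 1e-9)

  eth <- reducingEquivalentAudit(core, "ethanol")
  expect_equal(eth@nadh - acc@nadh, 2, tolerance = 1e-9)  # 2 extra NADH
  expect_equal(totalEquivalents(eth), 6, tolerance = 1e-9)
  # 6 equivalents x 2 electrons = the 12-electron reduction of 2 CO2 to
  # ethanol
  expect_equal(2 * totalEquivalents(eth), 12, tolerance = 1e-9)

  # the demand view is a property of the pathway, not of the hydrogenase
  ethNAD <- reducingEquivalentAudit(coreNAD, "ethanol")
  expect_equal(totalEquivalents(ethNAD), 6, tolerance = 1e-9)
})

test_that("supply view attributes equivalents to the electron donor", {
  co <- reducingEquivalentAudit(core, "ethanol", "co", interconverters = TRUE)
  expect_equal(co@fdx, 6, tolerance = 1e-8)    # all six as reduced Fd
  expect_equal(co@nadh + co@nadph, 0, tolerance = 1e-8)

  h2NADP <- reducingEquivalentAudit(core, "ethanol", "co2",
                                    interconverters = TRUE)
  expect_equal(h2NADP@nadph, 3, tolerance = 1e-8)  # equimolar split
  expect_equal(h2NADP@fdx, 3, tolerance = 1e-8)

  h2NAD <- reducingEquivalentAudit(coreNAD, "ethanol", "co2",
                                   interconverters = TRUE)
  expect_equal(h2NAD@nadh, 3, tolerance = 1e-8)    # 3 NADH + 3 Fd
  expect_equal(h2NAD@fdx, 3, tolerance = 1e-8)

  for (led in list(co, h2NADP, h2NAD))
    expect_equal(totalEquivalents(led), 6, tolerance = 1e-8)
})

test_that("Rnf/ATP-synthase yields per ethanol match the scenario accounting", {
  eNADP <- energyGapAnalysis(core, mediumPreset("h2_co2"), "ethanol", "ackA")
  expect_equal(eNADP@atpFromPmf, 1.5, tolerance = 1e-8)
  expect_equal(eNADP@rnfFlux, 3, tolerance = 1e-8)
  expect_equal(eNADP@atpDeficit, 0, tolerance = 1e-9)
  expect_equal(eNADP@atpSurplus, 0.5, tolerance = 1e-8)
  expect_true(eNADP@feasibleForGrowth)

  eNAD <- energyGapAnalysis(coreNAD, mediumPreset("h2_co2"), "ethanol",
                            "ackA")
  expect_equal(eNAD@atpFromPmf, 0.75, tolerance = 1e-8)
  expect_equal(eNAD@atpDeficit, 0.25, tolerance = 1e-8)
  expect_equal(eNAD@hydrogenaseFlux, 3, tolerance = 1e-8)
  expect_false(eNAD@feasibleForGrowth)

  eCO <- energyGapAnalysis(core, mediumPreset("co"), "ethanol", "ackA")
  expect_equal(eCO@atpFromPmf, 2.25, tolerance = 1e-8)
  expect_equal(eCO@rnfFlux, 4.5, tolerance = 1e-8)
  expect_equal(eCO@atpDeficit, 0, tolerance = 1e-9)
})

test_that("Rnf flux is unique across alternate optima in fixed-product scenarios", {
  scenario <- function(model) {
    m <- applyMedium(model, mediumPreset("h2_co2", coreConfig(model)))
    m <- knockoutGenes(m, "ackA")
    m <- setBounds(m, "BIOMASS", 0, 0)
    m <- setBounds(m, c("EX_ac", "EX_lac", "EX_btd", "EX_for"), 0, 0)
    m <- setBounds(m, "EX_h2", upper = 0)
    m <- setBounds(m, "EX_etoh", 1, 1)
    objectiveReaction(m) <- "EX_etoh"
    m
  }
  r <- fva(scenario(core), reactions = "RNF")
  expect_lt(r$max - r$min, 1e-8)
  expect_equal(r$min, 3, tolerance = 1e-8)
})

test_that("only the proton stoichiometry ratio matters for the ATP yield", {
  doubled <- buildCoreModel(coreModelConfig(rnfProtonsPerFd = 4,
                                            atpsProtonsPerAtp = 8))
  e <- energyGapAnalysis(doubled, mediumPreset("h2_co2",
                                               coreConfig(doubled)),
                         "ethanol", "ackA")
  expect_equal(e@atpFromPmf, 1.5, tolerance = 1e-8)
  expect_equal(e@atpSurplus, 0.5, tolerance = 1e-8)
})

test_that("acetate-kinase knockout panel reproduces the feasibility pattern", {
  panel <- ackaPanel()
  cell <- function(h, m) panel[panel$hydrogenase == h & panel$medium == m, ]
  expect_true(cell("NADP", "fructose")$feasible)
  expect_true(cell("NADP", "co")$feasible)
  expect_true(cell("NADP", "h2_co2")$feasible)
  expect_true(cell("NAD", "fructose")$feasible)
  expect_true(cell("NAD", "co")$feasible)
  expect_false(cell("NAD", "h2_co2")$feasible)
  # the knockout shifts flux from acetate towards ethanol on fructose
  expect_identical(cell("NADP", "fructose")$wildtypeProduct, "acetate")
  expect_identical(cell("NADP", "fructose")$knockoutProduct, "ethanol")
  # knockout reduces, but does not abolish, growth on fructose
  expect_lt(cell("NADP", "fructose")$knockoutGrowth,
            cell("NADP", "fructose")$wildtypeGrowth)
  expect_gt(cell("NADP", "fructose")$knockoutGrowth, 0)
})

test_that("nitrogen balance closes stoichiometrically on nitrate", {
  nit <- nitrateScenario(core)
  expect_equal(nit$no3Consumption,
               nit$nh4Secretion + nit$biomassNitrogen, tolerance = 1e-6)
  expect_gt(nit$nh4Secretion, 0)
  # deleting the nitrate pathway on ammonium-free nitrate medium removes
  # the only nitrogen source
  m <- applyMedium(core, mediumPreset("fructose_nitrate", coreConfig(core)))
  m <- knockoutGenes(m, c("narA", "nirB", "hcp"))
  sol <- fba(m)
  g <- if (solutionStatus(sol) == "optimal") objectiveValue(sol) else 0
  expect_equal(g, 0, tolerance = 1e-9)
})

test_that("substrate screen grows on all core substrates, slowest on formate", {
  scr <- substrateGrowthScreen(core)
  expect_true(all(scr$growth > 1e-6))
  expect_identical(scr$substrate[which.min(scr$growth)], "formate")
  expect_warning(substrateGrowthScreen(core, c("fructose", "methanol")),
                 "skipped")
})
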