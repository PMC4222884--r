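core <- buildCoreModel()
cfg <- coreConfig(core)

growthOn <- function(model, preset, ko = NULL, config = coreConfig(model)) {
  m <- applyMedium(model, mediumPreset(preset, config))
  if (!is.null(ko)) m <- knockoutGenes(m, ko)
  sol <- fba(m)
  if (solutionStatus(sol) != "optimal") 0 else max(objectiveValue(sol), 0)
}

test_that("every non-exchange, non-biomass core reaction is exactly balanced", {
  audit <- validateBalance(core)
  expect_true(all(audit$status %in% c("balanced", "exempt")))
  strict <- audit[audit$status == "balanced", ]
  for (el in c("C", "H", "O", "N", "P", "S", "Fe"))
    expect_true(all(strict[[el]] == 0))
  expect_true(all(strict$charge == 0))
})

test_that("heterotrophic and autotrophic growth are feasible", {
  for (p in c("fructose", "pyruvate", "formate"))
    expect_gt(growthOn(core, p), 1e-6)
  for (p in c("h2_co2", "co"))
    expect_gt(growthOn(core, p), 1e-6)
  # autotrophic growth on H2/CO2 secretes acetate
  sol <- parsimoniousFBA(applyMedium(core, mediumPreset("h2_co2", cfg)))
  expect_gt(fluxes(sol)[["EX_ac"]], 1e-6)
})

test_that("Rnf and Nfn are essential for autotrophic growth only", {
  for (ko in list("rnfC", "CLJU_c37240")) {
    expect_equal(growthOn(core, "h2_co2", ko), 0, tolerance = 1e-9)
    expect_equal(growthOn(core, "co", ko), 0, tolerance = 1e-9)
    expect_gt(growthOn(core, "fructose", ko), 1e-6)
  }
})

test_that("hydrogenase configs differ in exactly one reaction column", {
  nad <- buildCoreModel(coreModelConfig(hydrogenase = "NAD"))
  Sa <- as.matrix(stoichiometricMatrix(core))
  Sb <- as.matrix(stoichiometricMatrix(nad))
  differing <- colnames(Sa)[colSums(Sa != Sb) > 0]
  expect_identical(differing, "HYD")
  # the difference is confined to the NAD(H)/NADP(H) rows
  rows <- rownames(Sa)[Sa[, "HYD"] != Sb[, "HYD"]]
  expect_setequal(rows, c("nad_c", "nadh_c", "nadp_c", "nadph_c"))
})

test_that("configuration invariants are enforced", {
  expect_error(coreModelConfig(rnfProtonsPerFd = 8, atpsProtonsPerAtp = 4),
               class = "configError")
  expect_error(coreModelConfig(biomassAtp = -1), class = "configError")
  expect_error(mediumPreset("methanol"), class = "keyError")
  expect_error(buildCoreModel("not a config"), class = "configError")
})

test_that("medium presets encode the published uptake constraints", {
  m <- mediumPreset("h2_co2", cfg)
  expect_equal(m$EX_co2[1], -10)
  expect_equal(m$EX_h2[1], -20)
  m2 <- mediumPreset("co", cfg)
  expect_equal(m2$EX_co[1], -20)
  expect_false("EX_h2" %in% names(m2))  # H2 closed on CO medium
  m3 <- mediumPreset("fructose", cfg)
  expect_equal(m3$EX_fru[1], -1.88)
  m4 <- mediumPreset("fructose_nitrate", cfg)
  expect_false("EX_nh4" %in% names(m4))  # ammonium-free
  expect_lt(m4$EX_no3[1], 0)
})

test_that("homoacetogenic ceiling: three acetate per fructose", {
  # electron-complete refixation: 24 available electrons per fructose equal
  # exactly three 8-electron acetate units
  m <- applyMedium(core, mediumPreset("fructose", cfg, uptake = 1))
  m <- setBounds(m, c("BIOMASS", "EX_etoh", "EX_lac", "EX_btd", "EX_for",
                      "EX_h2"), 0, 0)
  objectiveReaction(m) <- "EX_ac"
  sol <- fba(m, "EX_ac")
  expect_equal(objectiveValue(sol), 3, tolerance = 1e-8)
})

test_that("acetate flux drops when nitrate replaces ammonium", {
  nit <- nitrateScenario(core)
  expect_lt(nit$acetateFluxNo3, nit$acetateFluxNh4)
  expect_lt(nit$relativeChange, 0)
})

test_that("the bundled JSON data file reproduces the built core model", {
  shipped <- readModel(coreModelFile())
  expect_identical(as.matrix(stoichiometricMatrix(shipped)),
                   as.matrix(stoichiometricMatrix(core)))
  expect_identical(reactions(shipped)$gpr, reactions(core)$gpr)
  expect_equal(growthOn(shipped, "fructose", config = cfg),
               growthOn(core, "fructose"), tolerance = 1e-9)
})
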