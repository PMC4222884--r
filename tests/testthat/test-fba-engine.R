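test_that("FBA solves bound-limited chains and detects infeasibility", {
  sol <- fba(chainModel(cap = 5))
  expect_identical(solutionStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 5, tolerance = 1e-9)
  # steady state and bounds hold tightly at the optimum
  m <- chainModel(5)
  expect_lt(max(abs(as.vector(stoichiometricMatrix(m) %*% fluxes(sol)))),
            1e-9)
  b <- bounds(m)
  expect_true(all(fluxes(sol) >= b$lower - 1e-9 &
                  fluxes(sol) <= b$upper + 1e-9))

  # no carbon source but a forced internal demand: infeasible
  closed <- setBounds(chainModel(5), "EX_a", lower = 0)
  closed <- setBounds(closed, "conv", lower = 1)
  expect_identical(solutionStatus(fba(closed)), "infeasible")
})

test_that("applyMedium closes unlisted uptakes and validates ids", {
  m <- chainModel(5)
  closed <- applyMedium(m, list())
  b <- bounds(closed)
  expect_true(all(b$lower[b$id %in% exchangeReactions(m)] >= 0))
  expect_equal(objectiveValue(fba(closed)), 0, tolerance = 1e-9)

  fed <- applyMedium(m, list(EX_a = c(-1.88, 0)))
  expect_equal(bounds(fed)$lower[bounds(fed)$id == "EX_a"], -1.88)
  expect_equal(objectiveValue(fba(fed)), 1.88, tolerance = 1e-9)

  expect_error(applyMedium(m, list(conv = c(-1, 0))), class = "keyError")
  expect_error(applyMedium(m, list(EX_zz = c(-1, 0))), class = "keyError")
})

test_that("FVA reports degeneracy and honours the objective fraction", {
  # linear chain at optimum: all ranges are points
  r <- fva(chainModel(5))
  expect_true(all(abs(r$max - r$min) < 1e-8))

  # two equivalent parallel paths: each spans [0, optimum]
  r2 <- fva(parallelModel(4))
  for (id in c("p1", "p2")) {
    expect_equal(r2$min[r2$id == id], 0, tolerance = 1e-8)
    expect_equal(r2$max[r2$id == id], 4, tolerance = 1e-8)
  }

  # fraction 0 equals unconstrained per-reaction min/max
  m <- chainModel(5)
  r3 <- fva(m, fraction = 0)
  expect_equal(r3$min[r3$id == "EX_a"], -5, tolerance = 1e-8)
  expect_equal(r3$max[r3$id == "EX_a"], 0, tolerance = 1e-8)
})

test_that("parsimonious FBA zeroes futile cycles and is deterministic", {
  m <- futileCycleModel(3)
  plain <- fba(m)
  p <- parsimoniousFBA(m)
  expect_equal(objectiveValue(p), objectiveValue(plain), tolerance = 1e-9)
  expect_equal(max(abs(fluxes(p)[c("cyc1", "cyc2")])), 0, tolerance = 1e-8)
  # total |v| is minimal: re-solve confirms no smaller total exists
  expect_equal(attr(p, "totalFlux"), 3 * 5, tolerance = 1e-6)

  # single-path network: identical to plain FBA
  ps <- parsimoniousFBA(chainModel(2))
  expect_equal(fluxes(ps), fluxes(fba(chainModel(2))), tolerance = 1e-8)

  # determinism
  expect_identical(fluxes(parsimoniousFBA(m)), fluxes(parsimoniousFBA(m)))
})

test_that("relaxing an uptake bound never decreases the optimum", {
  for (s in 1:10) {
    net <- randomFeasibleNetwork(2, 2, seed = s)
    m <- net@model
    base <- objectiveValue(fba(m))
    ex <- exchangeReactions(m)
    up <- ex[startsWith(ex, "EX_s")]
    for (id in up) {
      j <- match(id, reactions(m)$id)
      relaxed <- setBounds(m, id, lower = reactions(m)$lower[j] - 2)
      expect_gte(objectiveValue(fba(relaxed)), base - 1e-9)
    }
  }
})

test_that("single-gene deletion reports growth ratios", {
  m <- buildModel(
    rbind(metabolite("a_e", compartment = "e"),
          metabolite("b_e", compartment = "e"),
          metabolite("a_c"), metabolite("b_c")),
    list(reaction("EX_a", c(a_e = -1), -5, 0),
         reaction("At", c(a_e = -1, a_c = 1), 0, 1000, gpr = "tA"),
         reaction("p1", c(a_c = -1, b_c = 1), 0, 1000, gpr = "g1"),
         reaction("p2", c(a_c = -1, b_c = 1), 0, 2, gpr = "g2"),
         reaction("Bt", c(b_c = -1, b_e = 1), 0, 1000),
         reaction("EX_b", c(b_e = -1), 0, 1000)),
    genes = c("tA", "g1", "g2", "unused"),
    objective = "EX_b")
  res <- singleGeneDeletion(m)
  rr <- function(g) res$growthRatio[res$gene == g]
  expect_equal(rr("unused"), 1, tolerance = 1e-9)  # not in any GPR
  expect_equal(rr("tA"), 0, tolerance = 1e-9)      # sole transporter
  expect_equal(rr("g1"), 2 / 5, tolerance = 1e-9)  # capped alternate path
  expect_equal(rr("g2"), 1, tolerance = 1e-9)      # redundant path

  # a gene whose reactions carry no parsimonious flux and have zero-width
  # FVA ranges is phenotypically silent
  core <- applyMedium(buildCoreModel(), mediumPreset("fructose"))
  v <- fluxes(parsimoniousFBA(core))
  rBTD <- fva(core, reactions = "BTD")
  if (abs(v[["BTD"]]) < 1e-9 && abs(rBTD$max - rBTD$min) < 1e-8) {
    res2 <- singleGeneDeletion(core, "budA")
    expect_equal(res2$growthRatio, 1, tolerance = 1e-6)
  }
})

test_that("carbon entering via exchanges balances carbon leaving", {
  core <- buildCoreModel()
  cfg <- coreConfig(core)
  m <- applyMedium(core, mediumPreset("fructose", cfg))
  v <- fluxes(parsimoniousFBA(m))
  met <- metabolites(m)
  cIn <- 0
  for (id in exchangeReactions(m)) {
    S <- stoichiometricMatrix(m)
    metId <- rownames(S)[which(S[, id] != 0)]
    nC <- parseFormula(met$formula[met$id == metId])[["C"]]
    cIn <- cIn + nC * (-v[[id]])  # uptake positive
  }
  # biomass drains 2 carbons per acetyl-CoA incorporated
  cBiomass <- 2 * cfg@biomassAccoa * v[["BIOMASS"]]
  expect_equal(cIn, cBiomass, tolerance = 1e-6)
})
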