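test_that("an already-producing model needs no fill", {
  pool <- list(reaction("alt", c(a_c = -1, b_c = 1), 0, 1000))
  res <- gapfill(chainModel(5), pool, minObjective = 1e-3)
  expect_length(res, 1L)
  expect_length(res[[1]]@added, 0L)
})

test_that("a two-reaction gap is bridged, decoys excluded", {
  res <- gapfill(gappedChain(), gapPool(), minObjective = 1e-3,
                 maxSolutions = 10)
  expect_length(res, 1L)
  expect_setequal(res[[1]]@added, c("fill1", "fill2"))
  expect_gte(res[[1]]@restoredObjective, 1e-3)

  # minimality witness: dropping either member breaks producibility again
  for (drop in res[[1]]@added) {
    kept <- Filter(function(r) r$id %in% setdiff(res[[1]]@added, drop),
                   gapPool())
    m <- addReactions(gappedChain(), kept)
    sol <- fba(m)
    g <- if (solutionStatus(sol) == "optimal") objectiveValue(sol) else 0
    expect_lt(g, 1e-3)
  }
})

test_that("single-reaction cut on the core model is repaired", {
  core <- buildCoreModel()
  broken <- removeReactions(core, "FTHFLi")
  broken <- applyMedium(broken, mediumPreset("h2_co2"))
  pool <- list(
    reaction("FTHFL_pool", c(for_c = -1, thf_c = -1, atp_c = -1,
                             `10fthf_c` = 1, adp_c = 1, pi_c = 1), 0, 1000),
    reaction("decoy_lac", c(pyr_c = -1, lac_c = 1), 0, 1000))
  res <- gapfill(broken, pool, objective = "BIOMASS", minObjective = 1e-3)
  expect_identical(res[[1]]@added, "FTHFL_pool")
  # verified by re-running FBA on the repaired model
  repaired <- addReactions(broken, pool[1])
  expect_gt(objectiveValue(fba(repaired, "BIOMASS")), 1e-3)
})

test_that("enumeration matches exhaustive subset search on a 12-pool", {
  model <- gappedChain()
  pool <- gapPool(extraDecoys = 9)   # 12 candidates
  got <- gapfill(model, pool, minObjective = 1e-3, maxSolutions = Inf)
  ref <- enumerateFills(model, pool, "EX_d", 1e-3)
  norm <- function(sets) sort(vapply(sets, function(s)
    paste(sort(s), collapse = "+"), character(1)))
  expect_identical(norm(lapply(got, function(g) g@added)), norm(ref))
  # solutions are disjoint from reactions already in the model
  for (g in got)
    expect_length(intersect(g@added, reactions(model)$id), 0L)
})

test_that("an inadequate pool raises a no-fill error", {
  expect_error(gapfill(gappedChain(), gapPool()[3], minObjective = 1e-3),
               class = "noFillExistsError")
  expect_error(gapfill(gappedChain(), list(), minObjective = 1e-3),
               class = "noFillExistsError")
})
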