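test_that("random networks are reproducible with planted optima", {
  n1 <- randomFeasibleNetwork(1, 3, seed = 7)
  n2 <- randomFeasibleNetwork(1, 3, seed = 7)
  expect_identical(as.matrix(stoichiometricMatrix(n1@model)),
                   as.matrix(stoichiometricMatrix(n2@model)))
  expect_identical(n1@plantedOptimum, n2@plantedOptimum)
  expect_equal(objectiveValue(fba(n1@model)), n1@plantedOptimum,
               tolerance = 1e-9)

  n4 <- randomFeasibleNetwork(4, 2, seed = 1)
  caps <- -reactions(n4@model)$lower[startsWith(reactions(n4@model)$id,
                                                "EX_s")]
  expect_equal(n4@plantedOptimum, sum(caps))
  expect_equal(objectiveValue(fba(n4@model)), sum(caps), tolerance = 1e-9)

  expect_error(randomFeasibleNetwork(0, 2), class = "valueError")
  expect_error(randomFeasibleNetwork(2, 0), class = "valueError")
})

test_that("generation preserves the caller's RNG state", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(randomFeasibleNetwork(2, 2, seed = 9))
  expect_identical(stats::runif(1), before)
})

test_that("brute-force oracle agrees with planted optima and the engine", {
  net <- randomFeasibleNetwork(1, 3, seed = 7)
  expect_equal(bruteForceLPOracle(net@model), net@plantedOptimum,
               tolerance = 1e-6)

  for (s in 1:20) {
    cfgs <- list(c(1, 2), c(2, 2), c(1, 4), c(2, 1))
    cf <- cfgs[[1 + (s %% 4)]]
    net <- randomFeasibleNetwork(cf[1], cf[2], seed = 1000 + s)
    eng <- objectiveValue(fba(net@model))
    ora <- bruteForceLPOracle(net@model)
    expect_equal(eng, ora, tolerance = 1e-6)
    # the parsimonious solution is also optimal per oracle
    expect_equal(objectiveValue(parsimoniousFBA(net@model)), ora,
                 tolerance = 1e-6)
  }
})

test_that("oracle handles degenerate bounds and guards its scale", {
  m <- chainModel(5)
  zeroed <- setBounds(m, reactions(m)$id, lower = 0, upper = 0)
  expect_equal(bruteForceLPOracle(zeroed), 0, tolerance = 1e-12)

  big <- randomFeasibleNetwork(4, 2, seed = 2)  # 13 reactions
  expect_error(bruteForceLPOracle(big@model), class = "valueError")
})
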