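test_that("buildModel assembles and validates cross-references", {
  empty <- buildModel(NULL, list())
  expect_equal(dim(stoichiometricMatrix(empty)), c(0L, 0L))

  m <- chainModel()
  expect_s4_class(m, "MetabolicModel")
  expect_equal(nrow(metabolites(m)), 4L)
  expect_equal(nrow(reactions(m)), 5L)
  expect_setequal(exchangeReactions(m), c("EX_a", "EX_b"))

  expect_error(
    buildModel(rbind(metabolite("a_c")),
               list(reaction("r1", c(x_c = -1, a_c = 1)))),
    class = "referenceError")
  expect_error(
    buildModel(rbind(metabolite("a_c"), metabolite("a_c")),
               list(reaction("r1", c(a_c = -1)))),
    class = "duplicateIdError")
  expect_error(
    buildModel(rbind(metabolite("a_c")),
               list(reaction("r1", c(a_c = -1)), reaction("r1", c(a_c = 1)))),
    class = "duplicateIdError")
})

test_that("stoichiometric matrix holds signed coefficients losslessly", {
  m <- chainModel()
  S <- stoichiometricMatrix(m)
  expect_equal(as.numeric(S[c("a_c", "b_c"), "conv"]), c(-1, 1))
  # lossless reconstruction against independently stated stoichiometries
  stoich <- list(EX_a = c(a_e = -1), At = c(a_e = -1, a_c = 1),
                 conv = c(a_c = -1, b_c = 1), Bt = c(b_c = -1, b_e = 1),
                 EX_b = c(b_e = -1))
  for (id in names(stoich)) {
    col <- S[, id]
    expect_equal(col[col != 0][names(stoich[[id]])], stoich[[id]])
  }
})

test_that("setBounds and knockoutGenes constrain reactions", {
  m <- buildModel(rbind(metabolite("a_c")),
                  list(reaction("r1", c(a_c = 1), 0, 10, gpr = "gA and gB"),
                       reaction("r2", c(a_c = -1), 0, 10, gpr = "gA or gB")))
  ko <- knockoutGenes(m, "gA")
  b <- bounds(ko)
  expect_equal(b$upper[b$id == "r1"], 0)  # AND: silenced
  expect_equal(b$upper[b$id == "r2"], 10) # OR: isozyme remains
  expect_error(knockoutGenes(m, "nope"), class = "referenceError")
  expect_error(setBounds(m, "r1", lower = 5, upper = 1),
               class = "boundsError")
  expect_setequal(geneReactions(m, "gA"), c("r1", "r2"))
})

test_that("checkBalance audits elements and charge", {
  core <- buildCoreModel()
  # phosphotransacetylase with standard formulas, audited by hand:
  # accoa(C23H34N7O17P3S, -4) + pi(HO4P, -2) = actp(C2H3O5P, -2) +
  # coa(C21H32N7O16P3S, -4) nets to zero in every element and in charge
  b <- checkBalance(core, "PTAr")
  expect_identical(b$status, "balanced")
  expect_true(all(b$elements == 0))
  expect_identical(b$charge, 0)

  expect_identical(checkBalance(core, "EX_ac")$status, "exempt")
  expect_identical(checkBalance(core, "BIOMASS")$status, "exempt")

  m <- buildModel(rbind(metabolite("a_c", formula = "CH4"),
                        metabolite("b_c", formula = "CH5")),
                  list(reaction("bad", c(a_c = -1, b_c = 1), 0, 10)))
  bad <- checkBalance(m, "bad")
  expect_identical(bad$status, "imbalanced")
  expect_equal(unname(bad$elements["H"]), 1)

  lump <- buildModel(rbind(metabolite("a_c", formula = "CH4"),
                           metabolite("x_c", formula = "")),
                     list(reaction("r", c(a_c = -1, x_c = 1), 0, 10)))
  expect_warning(res <- checkBalance(lump, "r"), "lumped")
  expect_identical(res$status, "incomplete")
})

test_that("formula parser handles the model element alphabet", {
  f <- parseFormula("C6H12O6")
  expect_equal(unname(f[c("C", "H", "O")]), c(6, 12, 6))
  expect_equal(unname(parseFormula("Fe2S2")[c("Fe", "S")]), c(2, 2))
  expect_equal(unname(parseFormula("HO4P")[c("H", "O", "P")]), c(1, 4, 1))
  expect_false(attr(parseFormula(""), "defined"))
  expect_error(parseFormula("Xy3"), "malformed")
})

test_that("GPR evaluation matches direct tree evaluation on random trees", {
  expect_false(evaluateGPR("gA and gB", "gA"))
  expect_true(evaluateGPR("gA or gB", "gA"))
  expect_true(evaluateGPR("", "gA"))
  expect_error(parseGPR("gA and (gB or"), "unbalanced|malformed")

  set.seed(42)
  genes <- paste0("g", 1:4)
  for (i in 1:40) {
    rg <- randomGprTree(genes, depth = sample(1:4, 1))
    used <- gprGenes(rg$string)
    # full truth table over knockout subsets of the genes involved
    for (k in 0:length(used)) {
      combos <- utils::combn(used, k, simplify = FALSE)
      for (ko in combos)
        expect_identical(evaluateGPR(rg$string, ko), evalTreeRef(rg$tree, ko))
    }
  }
})
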