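# Gap-filling fixtures and the exhaustive reference enumerator.

# all minimum-cardinality subsets of the pool that restore the objective,
# found by direct subset enumeration
enumerateFills <- function(model, pool, objective, minObjective) {
  for (k in 0:length(pool)) {
    hits <- list()
    for (idx in utils::combn(seq_along(pool), k, simplify = FALSE)) {
      m <- if (k == 0) model else addReactions(model, pool[idx])
      sol <- fba(m, objective)
      if (solutionStatus(sol) == "optimal" &&
          objectiveValue(sol) >= minObjective)
        hits[[length(hits) + 1L]] <- vapply(pool[idx], `[[`, character(1),
                                            "id")
    }
    if (length(hits)) return(hits)
  }
  list()
}

gappedChain <- function() {
  # a_e -> a_c -> b_c -> c_c -> d_e with the two middle steps missing
  buildModel(
    rbind(metabolite("a_e", compartment = "e"),
          metabolite("d_e", compartment = "e"),
          metabolite("a_c"), metabolite("b_c"), metabolite("c_c"),
          metabolite("x_c"), metabolite("dead_c")),
    list(reaction("EX_a", c(a_e = -1), -5, 0),
         reaction("At", c(a_e = -1, a_c = 1), 0, 1000),
         reaction("s1", c(a_c = -1, b_c = 1), 0, 1000),
         reaction("s4", c(c_c = -1, d_e = 1), 0, 1000),
         reaction("EX_d", c(d_e = -1), 0, 1000)),
    objective = "EX_d")
}

gapPool <- function(extraDecoys = 0) {
  pool <- list(
    reaction("fill1", c(b_c = -1, x_c = 1), 0, 1000),
    reaction("fill2", c(x_c = -1, c_c = 1), 0, 1000),
    reaction("decoy", c(a_c = -1, dead_c = 1), 0, 1000))
  for (i in seq_len(extraDecoys))
    pool[[length(pool) + 1L]] <-
      reaction(sprintf("pad%d", i),
               stats::setNames(c(-1, 1), c("x_c", "b_c")), 0, 1000)
  pool
}
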