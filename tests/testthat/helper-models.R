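# Small fixture networks built in code.

# EX_a (uptake cap) -> a_e -> a_c -> b_c -> b_e -> EX_b
chainModel <- function(cap = 5) {
  buildModel(
    rbind(metabolite("a_e", compartment = "e"),
          metabolite("b_e", compartment = "e"),
          metabolite("a_c"), metabolite("b_c")),
    list(reaction("EX_a", c(a_e = -1), -cap, 0),
         reaction("At", c(a_e = -1, a_c = 1), 0, 1000),
         reaction("conv", c(a_c = -1, b_c = 1), 0, 1000),
         reaction("Bt", c(b_c = -1, b_e = 1), 0, 1000),
         reaction("EX_b", c(b_e = -1), 0, 1000)),
    objective = "EX_b")
}

# two equivalent internal routes a_c -> b_c
parallelModel <- function(cap = 4) {
  buildModel(
    rbind(metabolite("a_e", compartment = "e"),
          metabolite("b_e", compartment = "e"),
          metabolite("a_c"), metabolite("b_c")),
    list(reaction("EX_a", c(a_e = -1), -cap, 0),
         reaction("At", c(a_e = -1, a_c = 1), 0, 1000),
         reaction("p1", c(a_c = -1, b_c = 1), 0, 1000),
         reaction("p2", c(a_c = -1, b_c = 1), 0, 1000),
         reaction("Bt", c(b_c = -1, b_e = 1), 0, 1000),
         reaction("EX_b", c(b_e = -1), 0, 1000)),
    objective = "EX_b")
}

# chain plus a two-reaction futile cycle b_c <-> c_c
futileCycleModel <- function(cap = 3) {
  buildModel(
    rbind(metabolite("a_e", compartment = "e"),
          metabolite("b_e", compartment = "e"),
          metabolite("a_c"), metabolite("b_c"), metabolite("c_c")),
    list(reaction("EX_a", c(a_e = -1), -cap, 0),
         reaction("At", c(a_e = -1, a_c = 1), 0, 1000),
         reaction("conv", c(a_c = -1, b_c = 1), 0, 1000),
         reaction("cyc1", c(b_c = -1, c_c = 1), -1000, 1000),
         reaction("cyc2", c(c_c = -1, b_c = 1), -1000, 1000),
         reaction("Bt", c(b_c = -1, b_e = 1), 0, 1000),
         reaction("EX_b", c(b_e = -1), 0, 1000)),
    objective = "EX_b")
}

# random GPR tree of bounded depth; returns list(tree, string)
randomGprTree <- function(genes, depth) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    g <- sample(genes, 1)
    return(list(tree = list(gene = g), string = g))
  }
  op <- sample(c("and", "or"), 1)
  nk <- sample(2:3, 1)
  kids <- lapply(seq_len(nk), function(i) randomGprTree(genes, depth - 1))
  list(tree = list(op = op, children = lapply(kids, `[[`, "tree")),
       string = paste0("(", paste(vapply(kids, `[[`, character(1), "string"),
                                  collapse = paste0(" ", op, " ")), ")"))
}

# reference evaluator working directly on the generated tree structure,
# independent of the package's parser
evalTreeRef <- function(node, ko) {
  if (!is.null(node$gene)) return(!(node$gene %in% ko))
  vals <- vapply(node$children, evalTreeRef, logical(1), ko = ko)
  if (node$op == "and") all(vals) else any(vals)
}
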