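#' @include AllGenerics.R
NULL

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "acetofluxError")))
}

#' Describe a metabolite
#'
#' Convenience constructor for one row of the metabolite table.
#'
#' @param id unique short token, conventionally suffixed with the compartment
#'   (e.g. \code{"ac_c"}, \code{"ac_e"}).
#' @param name free-text name.
#' @param formula Hill formula string over C/H/O/N/P/S/Fe; \code{""} for
#'   lumped species with no defined composition.
#' @param charge signed integer charge.
#' @param compartment \code{"c"} (cytosol) or \code{"e"} (extracellular).
#' @return one-row data.frame.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0L,
                       compartment = "c") {
  data.frame(id = id, name = name, formula = formula,
             charge = as.integer(charge), compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Describe a reaction
#'
#' Convenience constructor for the reaction list consumed by [buildModel()].
#'
#' @param id unique short token (field abbreviations such as \code{FDH7},
#'   \code{FTHFLi}, \code{PTAr} are used in the core model).
#' @param stoichiometry named numeric vector, metabolite id to coefficient;
#'   negative coefficients are consumed.
#' @param lower,upper flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction rule string (\code{""} for none).
#' @param name free-text name.
#' @param subsystem free-text subsystem label.
#' @return list understood by [buildModel()].
#' @export
reaction <- function(id, stoichiometry, lower = -1000, upper = 1000,
                     gpr = "", name = id, subsystem = "") {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  list(id = id, stoichiometry = stoichiometry, lower = lower, upper = upper,
       gpr = gpr, name = name, subsystem = subsystem)
}

#' Build a validated metabolic model
#'
#' Assembles metabolite, reaction and gene inputs into a
#' \linkS4class{MetabolicModel}, constructing the sparse stoichiometric
#' matrix and verifying all cross-references.
#'
#' @param metabolites data.frame of metabolites (rbind of [metabolite()]
#'   rows), or a list of such rows.
#' @param reactions list of [reaction()] descriptions.
#' @param genes character vector of gene ids; defaults to the union of genes
#'   referenced by the GPR rules.
#' @param objective id of the objective reaction, or \code{NULL}.
#' @return a \linkS4class{MetabolicModel}.
#' @examples
#' m <- buildModel(
#'   rbind(metabolite("a_e", compartment = "e"), metabolite("a_c")),
#'   list(reaction("EX_a", c(a_e = -1), -5, 0),
#'        reaction("TA", c(a_e = -1, a_c = 1), 0, 1000)))
#' @export
buildModel <- function(metabolites, reactions, genes = NULL,
                       objective = NULL) {
  if (is.list(metabolites) && !is.data.frame(metabolites))
    metabolites <- do.call(rbind, metabolites)
  if (is.null(metabolites) || nrow(metabolites) == 0L)
    metabolites <- data.frame(id = character(0), name = character(0),
                              formula = character(0), charge = integer(0),
                              compartment = character(0),
                              stringsAsFactors = FALSE)
  gprGeneSet <- unique(unlist(lapply(reactions, function(r) gprGenes(r$gpr))))
  if (is.null(genes)) genes <- gprGeneSet
  genes <- unique(c(genes, gprGeneSet))
  metIds <- metabolites$id
  rxnIds <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(metIds))
    .err(paste0("duplicate metabolite id: ",
                paste(unique(metIds[duplicated(metIds)]), collapse = ", ")),
         "duplicateIdError")
  if (anyDuplicated(rxnIds))
    .err(paste0("duplicate reaction id: ",
                paste(unique(rxnIds[duplicated(rxnIds)]), collapse = ", ")),
         "duplicateIdError")
  if (length(intersect(metIds, rxnIds)))
    .err("metabolite and reaction ids overlap", "duplicateIdError")

  triplets <- lapply(seq_along(reactions), function(j) {
    st <- reactions[[j]]$stoichiometry
    st <- st[st != 0]
    unknown <- setdiff(names(st), metIds)
    if (length(unknown))
      .err(paste0("reaction ", rxnIds[j], " references unknown metabolite: ",
                  paste(unknown, collapse = ", ")), "referenceError")
    cbind(i = match(names(st), metIds), j = j, x = unname(st))
  })
  trip <- do.call(rbind, c(list(matrix(numeric(0), 0, 3,
                                       dimnames = list(NULL, c("i", "j", "x")))),
                           triplets))
  S <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                            dims = c(length(metIds), length(rxnIds)),
                            dimnames = list(metIds, rxnIds))
  rxnTab <- data.frame(
    id = rxnIds,
    name = vapply(reactions, function(r) r$name %||% r$id, character(1)),
    lower = vapply(reactions, function(r) as.numeric(r$lower), numeric(1)),
    upper = vapply(reactions, function(r) as.numeric(r$upper), numeric(1)),
    gpr = vapply(reactions, function(r) as.character(r$gpr %||% ""),
                 character(1)),
    subsystem = vapply(reactions, function(r) as.character(r$subsystem %||% ""),
                       character(1)),
    stringsAsFactors = FALSE
  )
  if (length(objective) && !objective %in% rxnIds)
    .err(paste0("objective reaction not in model: ", objective),
         "referenceError")
  new("MetabolicModel", metabolites = metabolites, reactions = rxnTab,
      stoichiometry = methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix"),
      genes = as.character(genes),
      objective = as.character(objective %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("genes", "MetabolicModel", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
          function(x) x@stoichiometry)

#' @rdname accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objective)

#' @rdname accessors
#' @export
setMethod("objectiveReaction<-", "MetabolicModel", function(x, value) {
  x@objective <- as.character(value)
  methods::validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(x) {
  S <- x@stoichiometry
  nz <- Matrix::colSums(S != 0)
  ext <- x@metabolites$compartment == "e"
  extHit <- Matrix::colSums((S != 0)[ext, , drop = FALSE])
  x@reactions$id[nz == 1L & extHit == 1L]
})

#' @rdname accessors
#' @export
setMethod("bounds", "MetabolicModel", function(x) {
  data.frame(id = x@reactions$id, lower = x@reactions$lower,
             upper = x@reactions$upper, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("setBounds", "MetabolicModel",
          function(x, reaction, lower = NULL, upper = NULL) {
  idx <- match(reaction, x@reactions$id)
  if (anyNA(idx))
    .err(paste0("unknown reaction: ",
                paste(reaction[is.na(idx)], collapse = ", ")),
         "referenceError")
  if (!is.null(lower)) x@reactions$lower[idx] <- lower
  if (!is.null(upper)) x@reactions$upper[idx] <- upper
  if (any(x@reactions$lower[idx] > x@reactions$upper[idx]))
    .err("lower bound above upper bound", "boundsError")
  x
})

#' Disable reactions silenced by a gene knockout
#'
#' Evaluates every GPR rule under the knockout set and sets the bounds of
#' inactivated reactions to zero.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param knockouts character vector of gene ids to delete.
#' @return the constrained model.
#' @export
knockoutGenes <- function(model, knockouts) {
  unknown <- setdiff(knockouts, model@genes)
  if (length(unknown))
    .err(paste0("unknown genes: ", paste(unknown, collapse = ", ")),
         "referenceError")
  off <- vapply(model@reactions$gpr,
                function(g) nzchar(g) && !evaluateGPR(g, knockouts),
                logical(1), USE.NAMES = FALSE)
  if (any(off))
    model <- setBounds(model, model@reactions$id[off], lower = 0, upper = 0)
  model
}

#' Reactions associated with a gene
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param gene gene id.
#' @return reaction ids whose GPR mentions the gene.
#' @export
geneReactions <- function(model, gene) {
  hit <- vapply(model@reactions$gpr, function(g) gene %in% gprGenes(g),
                logical(1), USE.NAMES = FALSE)
  model@reactions$id[hit]
}

#' Add reactions (and any new metabolites) to a model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reactions list of [reaction()] descriptions.
#' @param metabolites optional data.frame of new metabolites.
#' @return extended model.
#' @export
addReactions <- function(model, reactions, metabolites = NULL) {
  met <- model@metabolites
  if (!is.null(metabolites)) met <- rbind(met, metabolites)
  old <- .reactionList(model)
  buildModel(met, c(old, reactions), genes = model@genes,
             objective = if (length(model@objective)) model@objective else NULL)
}

#' Drop reactions from a model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param ids reaction ids to remove.
#' @return reduced model (metabolite table unchanged).
#' @export
removeReactions <- function(model, ids) {
  keep <- !(model@reactions$id %in% ids)
  obj <- model@objective
  if (length(obj) && !(obj %in% model@reactions$id[keep])) obj <- character(0)
  buildModel(model@metabolites, .reactionList(model)[keep],
             genes = model@genes,
             objective = if (length(obj)) obj else NULL)
}

.reactionList <- function(model) {
  S <- model@stoichiometry
  lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    st <- col[col != 0]
    r <- model@reactions[j, ]
    reaction(r$id, st, r$lower, r$upper, r$gpr, r$name, r$subsystem)
  })
}

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites, %d reactions, %d genes\n",
              nrow(object@metabolites), nrow(object@reactions),
              length(object@genes)))
  if (length(object@objective))
    cat("  objective:", object@objective, "\n")
  ex <- exchangeReactions(object)
  cat(sprintf("  exchanges: %d open to uptake: %d\n", length(ex),
              sum(object@reactions$lower[match(ex, object@reactions$id)] < 0)))
})

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution: %s", object@status))
  if (object@status == "optimal")
    cat(sprintf(", objective = %.6g", object@objectiveValue))
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxSolution", function(x) x@objectiveValue)

#' @rdname accessors
#' @export
setMethod("solutionStatus", "FluxSolution", function(x) x@status)
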