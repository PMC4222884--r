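#' @include model-build.R
NULL

.isExemptReaction <- function(model, id) {
  j <- match(id, model@reactions$id)
  id %in% exchangeReactions(model) ||
    grepl("^(BIOMASS|DM_|SK_)", id) ||
    identical(model@reactions$subsystem[j], "Biomass")
}

#' Audit the elemental and charge balance of a reaction
#'
#' Computes the per-element net atom count (sum of coefficient times atom
#' count over participating metabolites) plus the net charge. An all-zero
#' result means the reaction is balanced. Exchange reactions and biomass-type
#' drains move matter across the system boundary by design and are exempt.
#' Lumped metabolites without a formula are skipped with a warning and the
#' audit is flagged incomplete.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param id reaction id.
#' @return list with elements \code{status} (\code{"balanced"},
#'   \code{"imbalanced"}, \code{"exempt"} or \code{"incomplete"}),
#'   \code{elements} (named net counts over C/H/O/N/P/S/Fe) and
#'   \code{charge} (net charge).
#' @examples
#' m <- buildModel(
#'   rbind(metabolite("a_c", formula = "CH4"),
#'         metabolite("b_c", formula = "CH4")),
#'   list(reaction("iso", c(a_c = -1, b_c = 1), 0, 10)))
#' checkBalance(m, "iso")$status
#' @export
checkBalance <- function(model, id) {
  j <- match(id, model@reactions$id)
  if (is.na(j)) .err(paste0("unknown reaction: ", id), "referenceError")
  if (.isExemptReaction(model, id))
    return(list(status = "exempt",
                elements = stats::setNames(rep(0, length(.ELEMENTS)),
                                           .ELEMENTS),
                charge = 0))
  col <- model@stoichiometry[, j]
  st <- col[col != 0]
  met <- model@metabolites[match(names(st), model@metabolites$id), ]
  defined <- .formulaDefined(met$formula)
  if (any(!defined))
    warning("reaction ", id, " involves lumped species without formulas: ",
            paste(met$id[!defined], collapse = ", "), call. = FALSE)
  net <- stats::setNames(rep(0, length(.ELEMENTS)), .ELEMENTS)
  for (k in which(defined))
    net <- net + st[k] * parseFormula(met$formula[k])
  charge <- sum(st[defined] * met$charge[defined])
  status <- if (any(!defined)) "incomplete"
            else if (all(abs(net) < 1e-9) && abs(charge) < 1e-9) "balanced"
            else "imbalanced"
  list(status = status, elements = net, charge = charge)
}

#' Audit every reaction in a model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return data.frame with one row per reaction: id, status, and net counts
#'   for each element and charge.
#' @export
validateBalance <- function(model) {
  rows <- lapply(model@reactions$id, function(id) {
    b <- suppressWarnings(checkBalance(model, id))
    cbind(data.frame(id = id, status = b$status, stringsAsFactors = FALSE),
          as.data.frame(as.list(b$elements)), charge = b$charge)
  })
  do.call(rbind, rows)
}
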