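#' @include AllClasses.R
NULL

#' Accessors for MetabolicModel and FluxSolution objects
#'
#' \code{metabolites}, \code{reactions} and \code{genes} return the annotation
#' tables; \code{stoichiometricMatrix} the sparse metabolites x reactions
#' matrix; \code{objectiveReaction} the id of the objective;
#' \code{exchangeReactions} the ids of boundary exchanges; \code{fluxes},
#' \code{objectiveValue} and \code{solutionStatus} the components of a
#' \linkS4class{FluxSolution}.
#'
#' @param x a \linkS4class{MetabolicModel} or \linkS4class{FluxSolution}.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(x) standardGeneric("stoichiometricMatrix"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction",
           function(x) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction<-",
           function(x, value) standardGeneric("objectiveReaction<-"))

#' @rdname accessors
#' @export
setGeneric("exchangeReactions",
           function(x) standardGeneric("exchangeReactions"))

#' @rdname accessors
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))

#' @rdname accessors
#' @export
setGeneric("setBounds",
           function(x, reaction, lower = NULL, upper = NULL)
             standardGeneric("setBounds"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))

#' @rdname accessors
#' @export
setGeneric("totalEquivalents", function(x) standardGeneric("totalEquivalents"))
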