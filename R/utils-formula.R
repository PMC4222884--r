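## Chemical formula handling for balance auditing.
## Formulas are Hill-style strings over the element alphabet used by the core
## model (C, H, O, N, P, S, Fe). An empty string denotes a lumped species with
## no defined composition.

.ELEMENTS <- c("C", "H", "O", "N", "P", "S", "Fe")

#' Parse a chemical formula string into element counts
#'
#' @param formula a formula string such as \code{"C6H12O6"} or \code{"HPO4"};
#'   the empty string yields an all-zero count vector flagged as undefined.
#' @return named integer vector over C, H, O, N, P, S, Fe with attribute
#'   \code{defined} (FALSE for empty formulas).
#' @examples
#' parseFormula("C6H12O6")
#' parseFormula("Fe2S2")
#' @export
parseFormula <- function(formula) {
  counts <- stats::setNames(rep(0, length(.ELEMENTS)), .ELEMENTS)
  if (is.na(formula) || !nzchar(formula)) {
    attr(counts, "defined") <- FALSE
    return(counts)
  }
  rest <- formula
  pat <- "^(Fe|C|H|O|N|P|S)([0-9]*)"
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(pat, rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop("malformed formula: ", formula, call. = FALSE)
    el <- m[2]
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[el] <- counts[el] + n
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  attr(counts, "defined") <- TRUE
  counts
}

.formulaDefined <- function(formula) {
  !is.na(formula) & nzchar(formula)
}
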