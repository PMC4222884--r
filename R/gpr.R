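## Gene-protein-reaction (GPR) boolean rules.
## Rules are stored as strings in the COBRA dialect, e.g.
##   "CLJU_c37610 and CLJU_c37620", "(geneA and geneB) or geneC".
## An empty rule means "no gene association": the reaction can never be
## silenced by a gene knockout.

.gprTokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule into a boolean expression tree
#'
#' The tree is a nested list with nodes \code{list(op = "and"/"or",
#' children = list(...))} and leaves \code{list(gene = "id")}; \code{NULL}
#' represents the empty rule.
#'
#' @param rule GPR string; \code{and}/\code{or} keywords are case-insensitive.
#' @return parse tree, or \code{NULL} for an empty rule.
#' @export
parseGPR <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- .gprTokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parseOr <- function() {
    left <- parseAnd()
    children <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      children[[length(children) + 1L]] <- parseAnd()
    }
    if (length(children) == 1L) left else list(op = "or", children = children)
  }
  parseAnd <- function() {
    left <- parseAtom()
    children <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      children[[length(children) + 1L]] <- parseAtom()
    }
    if (length(children) == 1L) left else list(op = "and", children = children)
  }
  parseAtom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: ", rule, call. = FALSE)
    if (t == "(") {
      advance()
      inner <- parseOr()
      if (is.na(peek()) || peek() != ")")
        stop("unbalanced parentheses in GPR rule: ", rule, call. = FALSE)
      advance()
      return(inner)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule: ", rule, call. = FALSE)
    advance()
    list(gene = t)
  }
  tree <- parseOr()
  if (pos <= length(toks))
    stop("trailing tokens in GPR rule: ", rule, call. = FALSE)
  tree
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR string.
#' @return character vector of gene ids (empty for the empty rule).
#' @export
gprGenes <- function(rule) {
  tree <- parseGPR(rule)
  walk <- function(node) {
    if (is.null(node)) return(character())
    if (!is.null(node$gene)) return(node$gene)
    unlist(lapply(node$children, walk))
  }
  unique(walk(tree))
}

#' Evaluate a GPR rule under a gene knockout set
#'
#' A leaf is active iff its gene is not knocked out; \code{and} nodes require
#' all children active, \code{or} nodes any child; the empty rule is always
#' active.
#'
#' @param rule GPR string (or a pre-parsed tree from [parseGPR()]).
#' @param knockouts character vector of knocked-out gene ids.
#' @return logical: is the reaction still catalysable?
#' @examples
#' evaluateGPR("gA and gB", "gA")  # FALSE
#' evaluateGPR("gA or gB", "gA")   # TRUE
#' evaluateGPR("", "gA")           # TRUE
#' @export
evaluateGPR <- function(rule, knockouts = character()) {
  tree <- if (is.character(rule) || is.null(rule) ||
              (length(rule) == 1L && is.na(rule))) parseGPR(rule) else rule
  ev <- function(node) {
    if (is.null(node)) return(TRUE)
    if (!is.null(node$gene)) return(!(node$gene %in% knockouts))
    vals <- vapply(node$children, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(tree)
}
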