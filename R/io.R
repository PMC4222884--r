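#' @include core-model.R
NULL

.SCHEMA_VERSION <- "1.0"

.fmtErr <- function(msg, pointer = "") {
  .err(paste0(msg, if (nzchar(pointer)) paste0(" (at ", pointer, ")")),
       "formatError")
}

.modelDocument <- function(model, provenance = NULL) {
  cfg <- attr(model, "config")
  if (!is.null(cfg) && is.null(provenance$config))
    provenance$config <- list(
      hydrogenase = cfg@hydrogenase,
      rnfProtonsPerFd = cfg@rnfProtonsPerFd,
      atpsProtonsPerAtp = cfg@atpsProtonsPerAtp,
      biomassAccoa = cfg@biomassAccoa, biomassAtp = cfg@biomassAtp,
      biomassNadph = cfg@biomassNadph, biomassNh4 = cfg@biomassNh4,
      proteinFraction = cfg@proteinFraction, ngam = cfg@ngam,
      fructoseUptake = cfg@fructoseUptake)
  if (is.null(provenance)) provenance <- list(source = "acetoflux")
  if (is.null(provenance$source)) provenance$source <- "acetoflux"
  S <- model@stoichiometry
  rxns <- lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    st <- col[col != 0]
    r <- model@reactions[j, ]
    list(id = r$id, name = r$name, lower = r$lower, upper = r$upper,
         gpr = r$gpr, subsystem = r$subsystem,
         stoichiometry = as.list(st))
  })
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    list(id = m$id, name = m$name, formula = m$formula,
         charge = m$charge, compartment = m$compartment)
  })
  list(schema_version = .SCHEMA_VERSION, provenance = provenance,
       metabolites = mets, reactions = rxns,
       genes = as.list(model@genes),
       objective = if (length(model@objective)) model@objective else NULL)
}

#' Write a model to the package JSON schema
#'
#' The schema mirrors the widespread COBRA JSON dialect (metabolites,
#' reactions with stoichiometry maps and bounds, genes, objective) with an
#' added provenance block. Serialization is deterministic, so
#' write-read-write round trips are byte-identical.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file path.
#' @param provenance optional named list recorded in the provenance block.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path, provenance = NULL) {
  doc <- .modelDocument(model, provenance)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a model from the package JSON schema
#'
#' @param path file path.
#' @return a \linkS4class{MetabolicModel}; the provenance block is attached
#'   as attribute \code{"provenance"}, and a core-model configuration stored
#'   there is restored as attribute \code{"config"}.
#' @export
readModel <- function(path) {
  if (!file.exists(path)) .err(paste0("no such file: ", path),
                               "fileNotFoundError")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .fmtErr(paste0("unparseable JSON: ",
                                                     conditionMessage(e))))
  if (is.null(doc$schema_version)) .fmtErr("missing field", "/schema_version")
  if (!identical(doc$schema_version, .SCHEMA_VERSION))
    .fmtErr(paste0("unknown schema_version: ", doc$schema_version),
            "/schema_version")
  for (f in c("metabolites", "reactions", "genes"))
    if (is.null(doc[[f]])) .fmtErr("missing field", paste0("/", f))
  mets <- do.call(rbind, lapply(seq_along(doc$metabolites), function(i) {
    m <- doc$metabolites[[i]]
    for (f in c("id", "compartment"))
      if (is.null(m[[f]]))
        .fmtErr("missing field", sprintf("/metabolites/%d/%s", i - 1L, f))
    metabolite(m$id, m$name %||% m$id, m$formula %||% "",
               m$charge %||% 0L, m$compartment)
  }))
  rxns <- lapply(seq_along(doc$reactions), function(j) {
    r <- doc$reactions[[j]]
    for (f in c("id", "lower", "upper", "stoichiometry"))
      if (is.null(r[[f]]))
        .fmtErr("missing field", sprintf("/reactions/%d/%s", j - 1L, f))
    st <- unlist(r$stoichiometry)
    reaction(r$id, st, r$lower, r$upper, r$gpr %||% "", r$name %||% r$id,
             r$subsystem %||% "")
  })
  model <- buildModel(mets, rxns, genes = unlist(doc$genes),
                      objective = doc$objective)
  attr(model, "provenance") <- doc$provenance
  cfgDoc <- doc$provenance$config
  if (!is.null(cfgDoc))
    attr(model, "config") <- do.call(coreModelConfig, cfgDoc)
  model
}

.coreFormulaOk <- function(f) {
  !is.na(f) & grepl("^((Fe|C|H|O|N|P|S)[0-9]*)*$", f)
}

#' Load a published COBRA-dialect model
#'
#' Ingests a user-supplied genome-scale model (e.g. the published
#' C. ljungdahlii reconstruction iHN637) into the package's internal types,
#' preserving bounds, GPR rules and the objective. Supported dialects:
#' \code{cobra_json} (COBRA JSON) and \code{sbml} (SBML Level 3 with the
#' fbc package). MATLAB \code{.mat} files are not readable in this stack;
#' export such models to JSON or SBML first.
#'
#' @param path model file.
#' @param dialect \code{"cobra_json"} or \code{"sbml"} (\code{"cobra_mat"}
#'   is recognised but unsupported); default guessed from the extension.
#' @return a \linkS4class{MetabolicModel}; reports the gene/reaction/
#'   metabolite counts via \code{message()}.
#' @export
loadPublishedModel <- function(path, dialect = NULL) {
  if (!file.exists(path)) .err(paste0("no such file: ", path),
                               "fileNotFoundError")
  dialect <- dialect %||% switch(tolower(tools::file_ext(path)),
                                 json = "cobra_json",
                                 xml = "sbml", sbml = "sbml",
                                 mat = "cobra_mat",
                                 .fmtErr("cannot guess dialect from extension"))
  model <- switch(dialect,
    cobra_json = .loadCobraJson(path),
    sbml = .loadSbml(path),
    cobra_mat = .fmtErr("MAT dialect unsupported; export to JSON or SBML"),
    .fmtErr(paste0("unknown dialect: ", dialect)))
  message(sprintf("loaded model: %d genes, %d reactions, %d metabolites",
                  length(model@genes), nrow(model@reactions),
                  nrow(model@metabolites)))
  model
}

.loadCobraJson <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .fmtErr(paste0("unparseable JSON: ",
                                                     conditionMessage(e))))
  for (f in c("metabolites", "reactions"))
    if (is.null(doc[[f]])) .fmtErr("missing field", paste0("/", f))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    comp <- m$compartment %||%
      (if (grepl("_e$", m$id)) "e" else "c")
    if (!comp %in% c("c", "e"))
      comp <- if (grepl("_e$", m$id)) "e" else "c"
    f <- as.character(m$formula %||% "")
    if (length(f) == 0 || is.na(f) || !.coreFormulaOk(f)) f <- ""
    metabolite(m$id, m$name %||% m$id, f, round(m$charge %||% 0), comp)
  }))
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (isTRUE((r$objective_coefficient %||% 0) != 0))
      objective <<- r$id
    reaction(r$id, unlist(r$metabolites),
             r$lower_bound %||% -1000, r$upper_bound %||% 1000,
             r$gene_reaction_rule %||% "", r$name %||% r$id,
             r$subsystem %||% "")
  })
  geneIds <- vapply(doc$genes %||% list(), function(g)
    if (is.list(g)) g$id else as.character(g), character(1))
  buildModel(mets, rxns, genes = geneIds, objective = objective)
}

.sbmlGpr <- function(node) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .sbmlGpr, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

.loadSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) .fmtErr(paste0("unparseable XML: ",
                                                     conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pmap <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  spn <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(spn)) .fmtErr("no species found", "/listOfSpecies")
  mets <- do.call(rbind, lapply(spn, function(s) {
    id <- sub("^M_", "", xml2::xml_attr(s, "id"))
    comp <- xml2::xml_attr(s, "compartment")
    if (is.na(comp) || !comp %in% c("c", "e"))
      comp <- if (grepl("_e$", id)) "e" else "c"
    ch <- xml2::xml_attr(s, "charge")
    f <- xml2::xml_attr(s, "chemicalFormula")
    if (is.na(f) || !.coreFormulaOk(f)) f <- ""
    metabolite(id, xml2::xml_attr(s, "name") %|NA|% id, f,
               as.integer(ch %|NA|% "0"), comp)
  }))
  rn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  objId <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']"),
    "reaction")
  objective <- if (!is.na(objId)) sub("^R_", "", objId) else NULL
  rxns <- lapply(rn, function(r) {
    id <- sub("^R_", "", xml2::xml_attr(r, "id"))
    st <- numeric(0)
    for (sr in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      sp <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[sp] <- -(as.numeric(xml2::xml_attr(sr, "stoichiometry") %|NA|% "1"))
    }
    for (sr in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      sp <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[sp] <- (st[sp] %|NA0|% 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %|NA|% "1")
    }
    lo <- pmap[xml2::xml_attr(r, "lowerFluxBound")]
    hi <- pmap[xml2::xml_attr(r, "upperFluxBound")]
    if (is.na(lo))
      lo <- if (identical(xml2::xml_attr(r, "reversible"), "true"))
        -1000 else 0
    if (is.na(hi)) hi <- 1000
    gprNode <- xml2::xml_find_first(
      r, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (inherits(gprNode, "xml_node")) .sbmlGpr(gprNode) else ""
    reaction(id, st, unname(lo), unname(hi), gpr,
             xml2::xml_attr(r, "name") %|NA|% id, "")
  })
  gp <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  geneIds <- sub("^G_", "", xml2::xml_attr(gp, "id"))
  buildModel(mets, rxns, genes = geneIds, objective = objective)
}

`%|NA|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
`%|NA0|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

#' The bundled core model data file
#'
#' Path to the versioned JSON serialization of the default core model
#' shipped with the package (readable with [readModel()]).
#'
#' @return file path.
#' @export
coreModelFile <- function() {
  system.file("extdata", "clj_core_model.json", package = "acetoflux",
              mustWork = TRUE)
}
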