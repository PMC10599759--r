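#' Read a constraint-based model from disk
#'
#' Two on-disk dialects are supported. `"json"` follows the common
#' constraint-based JSON layout (one record per reaction with a
#' metabolite:coefficient map, bounds, `gene_reaction_rule` and
#' `objective_coefficient`) with one extra per-reaction annotation,
#' `cell_label`. `"sbml"` is SBML Level 3 with per-reaction flux-bound
#' parameters; cell labels, objective coefficients and GPR strings are carried
#' in per-reaction annotation attributes.
#'
#' @param path file to read.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("cannot read model file: ", path)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a constraint-based model to disk
#'
#' The JSON dialect round-trips every field of the model exactly; the SBML
#' dialect preserves stoichiometry, bounds, GPR strings, objective
#' coefficients and cell labels.
#'
#' @param model a [metabolic_model()].
#' @param path destination file.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$reactions) || length(doc$reactions) == 0L) {
    stop("model file has no reactions: ", path)
  }
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  compartment <- vapply(doc$metabolites, function(m) {
    if (is.null(m$compartment)) NA_character_ else m$compartment
  }, character(1))
  if (anyNA(compartment)) compartment <- infer_compartment(met_ids)
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  n <- length(rxn_ids); m <- length(met_ids)
  S <- matrix(0, m, n, dimnames = list(met_ids, rxn_ids))
  for (j in seq_len(n)) {
    coef <- doc$reactions[[j]]$metabolites
    if (length(coef)) S[names(coef), j] <- vapply(coef, as.numeric, numeric(1))
  }
  getf <- function(field, default) vapply(doc$reactions, function(r) {
    if (is.null(r[[field]])) default else r[[field]]
  }, default)
  lb <- getf("lower_bound", NA_real_)
  ub <- getf("upper_bound", NA_real_)
  if (anyNA(lb) || anyNA(ub)) stop("reaction missing flux bounds in ", path)
  gpr <- getf("gene_reaction_rule", "")
  obj <- getf("objective_coefficient", 0)
  cell <- getf("cell_label", NA_character_)
  if (anyNA(cell)) cell <- infer_cell_label(rxn_ids)
  metabolic_model(met_ids, rxn_ids, S, lb, ub, obj, cell, gpr, compartment)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_along(model$metabolite_ids), function(i) {
    list(id = model$metabolite_ids[i], compartment = model$compartment[i])
  })
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$S[, j] != 0)
    coef <- as.list(model$S[nz, j])
    names(coef) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j],
         metabolites = coef,
         lower_bound = model$lower_bounds[j],
         upper_bound = model$upper_bounds[j],
         gene_reaction_rule = model$gpr[j],
         objective_coefficient = model$objective_coefficients[j],
         cell_label = model$cell_label[j])
  })
  genes <- lapply(model_genes(model), function(g) list(id = g))
  doc <- list(id = "neurometnet_model", metabolites = mets,
              reactions = rxns, genes = genes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    '<model id="neurometnet_model">',
    '<listOfCompartments>',
    sprintf('<compartment id="%s" constant="true"/>',
            unique(model$compartment)),
    '</listOfCompartments>',
    '<listOfSpecies>',
    sprintf('<species id="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            esc(model$metabolite_ids), esc(model$compartment)),
    '</listOfSpecies>',
    '<listOfParameters>',
    sprintf('<parameter id="lb_%d" value="%s" constant="true"/>',
            seq_along(model$reaction_ids), num(model$lower_bounds)),
    sprintf('<parameter id="ub_%d" value="%s" constant="true"/>',
            seq_along(model$reaction_ids), num(model$upper_bounds)),
    '</listOfParameters>',
    '<listOfReactions>')
  for (j in seq_along(model$reaction_ids)) {
    sj <- model$S[, j]
    react <- which(sj < 0); prod <- which(sj > 0)
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" lowerFluxBound="lb_%d" upperFluxBound="ub_%d" geneAssociation="%s" cellLabel="%s" objectiveCoefficient="%s">',
      esc(model$reaction_ids[j]),
      tolower(model$lower_bounds[j] < 0), j, j,
      esc(model$gpr[j]), esc(model$cell_label[j]),
      num(model$objective_coefficients[j])))
    if (length(react)) {
      lines <- c(lines, '<listOfReactants>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(model$metabolite_ids[react]), num(-sj[react])),
                 '</listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '<listOfProducts>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(model$metabolite_ids[prod]), num(sj[prod])),
                 '</listOfProducts>')
    }
    lines <- c(lines, '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>', '</model>', '</sbml>')
  writeLines(lines, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(sp, "id")
  compartment <- xml2::xml_attr(sp, "compartment")
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- as.numeric(xml2::xml_attr(pars, "value"))
  names(parval) <- xml2::xml_attr(pars, "id")
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0L) stop("model file has no reactions: ", path)
  rxn_ids <- xml2::xml_attr(rx, "id")
  n <- length(rxn_ids); m <- length(met_ids)
  S <- matrix(0, m, n, dimnames = list(met_ids, rxn_ids))
  for (j in seq_len(n)) {
    for (node in xml2::xml_find_all(rx[[j]], "./listOfReactants/speciesReference")) {
      S[xml2::xml_attr(node, "species"), j] <-
        S[xml2::xml_attr(node, "species"), j] - as.numeric(xml2::xml_attr(node, "stoichiometry"))
    }
    for (node in xml2::xml_find_all(rx[[j]], "./listOfProducts/speciesReference")) {
      S[xml2::xml_attr(node, "species"), j] <-
        S[xml2::xml_attr(node, "species"), j] + as.numeric(xml2::xml_attr(node, "stoichiometry"))
    }
  }
  lb <- parval[xml2::xml_attr(rx, "lowerFluxBound")]
  ub <- parval[xml2::xml_attr(rx, "upperFluxBound")]
  if (anyNA(lb) || anyNA(ub)) stop("missing flux-bound parameters in ", path)
  gpr <- xml2::xml_attr(rx, "geneAssociation")
  gpr[is.na(gpr)] <- ""
  cell <- xml2::xml_attr(rx, "cellLabel")
  if (anyNA(cell)) cell <- infer_cell_label(rxn_ids)
  obj <- as.numeric(xml2::xml_attr(rx, "objectiveCoefficient"))
  obj[is.na(obj)] <- 0
  metabolic_model(met_ids, rxn_ids, S, unname(lb), unname(ub), obj, cell, gpr,
                  compartment)
}

#' Read a differential-expression table
#'
#' Expects a UTF-8, tab-delimited file with header columns `gene_id`,
#' `effect`, `significance`, `cell`, `condition`. `effect` is the fold change
#' (stimulated/basal) for the neurotransmission condition and the age
#' coefficient for the aging condition; `significance` is the adjusted p /
#' FDR in `[0, 1]`.
#'
#' @param path TSV file.
#' @return a validated `data.frame`.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(de)
}

#' @rdname read_de_table
#' @param de a DE data.frame to validate.
#' @export
validate_de_table <- function(de) {
  need <- c("gene_id", "effect", "significance", "cell", "condition")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  if (any(de$significance < 0 | de$significance > 1)) {
    stop("significance values outside [0, 1]")
  }
  nt <- de$condition == "neurotransmission"
  if (any(de$effect[nt] <= 0)) stop("fold changes must be positive")
  if (anyDuplicated(de[, c("gene_id", "cell", "condition")])) {
    stop("duplicate (gene, cell, condition) rows in DE table")
  }
  de
}

#' Write a differential-expression table
#' @param de DE data.frame.
#' @param path destination TSV.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(validate_de_table(de), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT")
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute).
#' @param path destination file.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a two-column ortholog/identifier mapping table
#'
#' @param path TSV with header columns `source` and `target`; one-to-many
#'   mappings are given as repeated `source` rows.
#' @return data.frame with columns `source`, `target`.
#' @export
read_mapping <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(map))) {
    stop("mapping table must have columns 'source' and 'target'")
  }
  map[, c("source", "target")]
}
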