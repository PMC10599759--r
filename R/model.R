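#' Construct a two-cell constraint-based metabolic model
#'
#' A `MetabolicModel` holds the stoichiometric matrix together with flux
#' bounds, the linear objective, per-reaction cell labels and gene-reaction
#' (GPR) association strings. It is the common currency of the whole
#' pipeline: FBA, the reaction projection and the gene-level integration all
#' consume this object.
#'
#' @param metabolite_ids character vector of metabolite identifiers (rows of `S`).
#' @param reaction_ids character vector of reaction identifiers (columns of `S`).
#' @param S numeric matrix, metabolites x reactions; dimensionless
#'   stoichiometric coefficients.
#' @param lower_bounds,upper_bounds numeric per-reaction flux bounds (uM/s).
#'   Must be finite: constraint-based models bound every flux.
#' @param objective_coefficients numeric per-reaction objective weights.
#' @param cell_label character per-reaction tag; one of `"neuron"`,
#'   `"astrocyte"`, `"exchange"`. When `NULL`, inferred from the reaction id
#'   suffix (`"_n"` / `"_a"`), defaulting to `"exchange"`.
#' @param gpr character per-reaction boolean gene association (e.g.
#'   `"(g1 and g2) or g3"`); `""` for spontaneous/boundary reactions.
#' @param compartment character per-metabolite tag; when `NULL`, inferred from
#'   the metabolite id suffix.
#'
#' @return An object of class `MetabolicModel` (a validated list).
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S,
                            lower_bounds, upper_bounds,
                            objective_coefficients = NULL,
                            cell_label = NULL, gpr = NULL,
                            compartment = NULL) {
  S <- as.matrix(S)
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  if (is.null(objective_coefficients)) {
    objective_coefficients <- numeric(length(reaction_ids))
  }
  if (is.null(cell_label)) cell_label <- infer_cell_label(reaction_ids)
  if (is.null(gpr)) gpr <- rep("", length(reaction_ids))
  if (is.null(compartment)) compartment <- infer_compartment(metabolite_ids)
  model <- structure(
    list(
      metabolite_ids = as.character(metabolite_ids),
      reaction_ids = as.character(reaction_ids),
      S = S,
      lower_bounds = as.numeric(lower_bounds),
      upper_bounds = as.numeric(upper_bounds),
      objective_coefficients = as.numeric(objective_coefficients),
      cell_label = as.character(cell_label),
      gpr = as.character(gpr),
      compartment = as.character(compartment)
    ),
    class = "MetabolicModel"
  )
  validate_model(model)
  model
}

#' Validate a MetabolicModel
#'
#' Checks the structural invariants: matching dimensions, unique identifiers,
#' finite and consistently ordered bounds (`lb <= ub`, reported by reaction
#' id), and a non-empty reaction list.
#'
#' @param model a [metabolic_model()] object.
#' @return the model, invisibly, if valid; otherwise an error.
#' @export
validate_model <- function(model) {
  n <- length(model$reaction_ids)
  m <- length(model$metabolite_ids)
  if (n == 0L) stop("model has an empty reaction list")
  if (anyDuplicated(model$reaction_ids)) stop("duplicate reaction ids")
  if (anyDuplicated(model$metabolite_ids)) stop("duplicate metabolite ids")
  if (!all(dim(model$S) == c(m, n))) {
    stop(sprintf("S has dimension %d x %d, expected %d x %d",
                 nrow(model$S), ncol(model$S), m, n))
  }
  for (fld in c("lower_bounds", "upper_bounds", "objective_coefficients",
                "cell_label", "gpr")) {
    if (length(model[[fld]]) != n) {
      stop(sprintf("%s has length %d, expected %d", fld, length(model[[fld]]), n))
    }
  }
  if (length(model$compartment) != m) {
    stop("compartment has wrong length")
  }
  if (any(!is.finite(c(model$S, model$objective_coefficients)))) {
    stop("model contains non-finite stoichiometry or objective entries")
  }
  if (anyNA(model$lower_bounds) || anyNA(model$upper_bounds)) {
    stop("model contains missing bounds")
  }
  bad <- which(model$lower_bounds > model$upper_bounds)
  if (length(bad)) {
    stop(sprintf("lower bound exceeds upper bound for reaction(s): %s",
                 paste(model$reaction_ids[bad], collapse = ", ")))
  }
  invisible(model)
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions\n",
              length(x$metabolite_ids), length(x$reaction_ids)))
  cat(sprintf("  cells: %s\n",
              paste(sprintf("%s (%d)", names(table(x$cell_label)),
                            table(x$cell_label)), collapse = ", ")))
  cat(sprintf("  objective on: %s\n",
              paste(x$reaction_ids[x$objective_coefficients != 0],
                    collapse = ", ")))
  invisible(x)
}

infer_cell_label <- function(reaction_ids) {
  ifelse(grepl("_n$", reaction_ids), "neuron",
         ifelse(grepl("_a$", reaction_ids), "astrocyte", "exchange"))
}

infer_compartment <- function(metabolite_ids) {
  ifelse(grepl("_n$", metabolite_ids), "neuron",
         ifelse(grepl("_a$", metabolite_ids), "astrocyte", "extracellular"))
}

#' Extract gene identifiers from a gene-reaction association string
#'
#' GPR strings are boolean expressions over gene tokens (`and`/`or`,
#' case-insensitive, with parentheses). For hub-gene derivation only the set
#' of participating genes matters, so the boolean structure is flattened.
#'
#' @param expression a GPR string; `""` yields an empty set.
#' @return character vector of unique gene ids (sorted).
#' @export
#' @examples
#' parse_gpr("(g1 and g2) or g3")
parse_gpr <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  if (is.na(expression) || !nzchar(trimws(expression))) return(character(0))
  open <- lengths(regmatches(expression, gregexpr("\\(", expression)))
  close <- lengths(regmatches(expression, gregexpr("\\)", expression)))
  if (open != close) stop("unbalanced parentheses in GPR: ", expression)
  tokens <- strsplit(gsub("[()]", " ", expression), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tolower(tokens) %in% c("and", "or")]
  sort(unique(tokens))
}

#' All genes of a model
#'
#' @param model a [metabolic_model()] object.
#' @return sorted character vector of every gene appearing in any GPR.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$gpr, parse_gpr))))
}
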