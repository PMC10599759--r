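#' Default currency metabolites excluded from the reaction projection
#'
#' ATP/ADP and inorganic phosphate participate in nearly every
#' energy-coupled reaction; keeping them would weld the projection into one cofactor clique and wash
#' out the substrate backbone the centrality analysis probes.
#'
#' @param model a [metabolic_model()].
#' @return character vector of metabolite ids.
#' @export
currency_metabolites <- function(model) {
  grep("^(atp|adp|pi)_", model$metabolite_ids, value = TRUE)
}

#' Run the integrative hub-gene pipeline on a two-cell model
#'
#' End-to-end orchestration of the analysis: fit the astrocytic glycolytic
#' bound to the neuronal ATP demand, solve the coupled-objective FBA, extract
#' the sensitivity set from the reduced costs, score reactions by Absolute
#' Optimality, build the reaction projection and score every node's induced
#' centralities aggregated into the Absolute Centrality Contribution, merge
#' the per-cell top-percentile optimal and central reactions into hub genes,
#' intersect with the differential-expression table per stratum into
#' differential hub genes, and (optionally) run over-representation analysis
#' and the correlation/clustering QC.
#'
#' @param model a [metabolic_model()].
#' @param de_table DE data.frame (see [read_de_table()]); `NULL` skips the
#'   DHG stage.
#' @param gene_sets named list of gene sets for enrichment; `NULL` skips.
#' @param mapping optional two-column mapping table applied to hub genes
#'   before the DHG intersection.
#' @param q percentile for both the optimal and the central cutoff
#'   (default 90).
#' @param atp_demand neuronal ATP demand used to fit the astrocytic bound;
#'   `NULL` skips the fitting step.
#' @param fit_uptake_rxn astrocytic glucose-uptake reaction whose bound is
#'   fitted.
#' @param exclude_metabolites metabolites dropped from the projection
#'   (default [currency_metabolites()]).
#' @param qc_betweenness add betweenness as a fourth induced-centrality
#'   metric of the clustering QC (never part of the ACC aggregation). Off by
#'   default: the three normative metrics carry the cell signal.
#' @return list with the intermediate and final products: `model`,
#'   `solution`, `sensitivity`, `ao`, `graph`, `induced`, `acc`,
#'   `optimal_rxns`, `central_rxns`, `hub`, `dhg`, `enrichment`, `qc`,
#'   `wilcoxon`.
#' @export
run_hub_pipeline <- function(model, de_table = NULL, gene_sets = NULL,
                             mapping = NULL, q = 90,
                             atp_demand = fba_constants()$total_atp_demand,
                             fit_uptake_rxn = "GLCt_a",
                             exclude_metabolites = currency_metabolites(model),
                             qc_betweenness = FALSE) {
  if (!is.null(atp_demand) && fit_uptake_rxn %in% model$reaction_ids) {
    model <- fit_astrocytic_glycolysis(model, atp_demand,
                                       uptake_rxn = fit_uptake_rxn)$model
  }
  solution <- solve_fba(model)
  if (!identical(solution$status, "optimal")) {
    stop("FBA is ", solution$status, "; cannot run the pipeline")
  }
  sens <- extract_sensitivity_set(solution)
  ao <- optimality_table(model, solution, q = q)
  graph <- project_reactions(model, exclude_metabolites)
  metrics <- c("eigenvector", "closeness", "information")
  induced <- suppressWarnings(
    as.data.frame(lapply(stats::setNames(metrics, metrics), function(m) {
      induced_centrality(graph, sens$s, m)
    })))
  induced$reaction_id <- rownames(induced)
  acc <- aggregate_acc(induced, igraph::V(graph)$cell_label, q = q)
  optimal_rxns <- ao$reaction_id[ao$is_optimal]
  central_rxns <- acc$reaction_id[acc$is_central]
  hub <- hub_genes(model, optimal_rxns, central_rxns)
  hub_set <- hub$genes
  mapped <- NULL
  if (!is.null(mapping)) {
    mapped <- map_gene_ids(hub_set, mapping)
    hub_set <- mapped$mapped
  }
  dhg <- if (!is.null(de_table)) derive_dhg(hub_set, de_table) else NULL
  enrichment <- NULL
  if (!is.null(gene_sets) && !is.null(dhg)) {
    background <- model_genes(model)
    query <- unique(unlist(lapply(dhg$strata, `[[`, "gene")))
    enrichment <- enrich_gene_sets(intersect(query, background), background,
                                   gene_sets)
  }
  qc_metrics <- induced[, metrics]
  if (qc_betweenness) {
    qc_metrics$betweenness <- suppressWarnings(
      induced_centrality(graph, sens$s, "betweenness"))
  }
  qc <- suppressWarnings(
    correlation_clustering(qc_metrics, igraph::V(graph)$cell_label))
  wilcoxon <- rank_sum_compare(acc$acc, acc$cell_label)
  list(model = model, solution = solution, sensitivity = sens, ao = ao,
       graph = graph, induced = induced, acc = acc,
       optimal_rxns = optimal_rxns, central_rxns = central_rxns,
       hub = hub, mapped = mapped, dhg = dhg, enrichment = enrichment,
       qc = qc, wilcoxon = wilcoxon)
}
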