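#' Hub genes: genes behind the optimal and central reactions
#'
#' Merges the optimal and central reaction sets and expands their GPR strings
#' into the union of associated genes, recording per gene which source set(s)
#' and reactions contributed it.
#'
#' @param model a [metabolic_model()].
#' @param optimal_rxns,central_rxns character vectors of reaction ids (each a
#'   subset of the model's reactions).
#' @return list with `genes` (sorted character vector) and `provenance`
#'   (data.frame gene/reaction/source).
#' @export
hub_genes <- function(model, optimal_rxns, central_rxns) {
  all_rxns <- union(optimal_rxns, central_rxns)
  bad <- setdiff(all_rxns, model$reaction_ids)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  prov <- list()
  for (r in all_rxns) {
    g <- parse_gpr(model$gpr[match(r, model$reaction_ids)])
    if (!length(g)) next  # empty GPR contributes nothing
    src <- paste(c("optimal", "central")[c(r %in% optimal_rxns,
                                           r %in% central_rxns)],
                 collapse = "+")
    prov[[r]] <- data.frame(gene = g, reaction = r, source = src,
                            stringsAsFactors = FALSE)
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(0), reaction = character(0),
               source = character(0))
  rownames(prov) <- NULL
  list(genes = sort(unique(prov$gene)), provenance = prov)
}

#' Map gene identifiers through an ortholog/ID table
#'
#' @param genes character vector of source gene ids.
#' @param mapping data.frame with columns `source`, `target` (one-to-many as
#'   repeated `source` rows).
#' @return list with `mapped` (sorted targets of mapped sources) and
#'   `unmapped` (source ids without any mapping).
#' @export
map_gene_ids <- function(genes, mapping) {
  if (!all(c("source", "target") %in% names(mapping))) {
    stop("mapping must have columns 'source' and 'target'")
  }
  if (!nrow(mapping) && length(genes)) {
    warning("empty mapping table; all genes unmapped")
  }
  hit <- mapping$source %in% genes
  list(mapped = sort(unique(mapping$target[hit])),
       unmapped = sort(setdiff(genes, mapping$source)))
}

#' Differential-expression thresholds per condition
#'
#' The neurotransmission condition uses fold changes: up if
#' `FC >= 1.3`, down if `FC <= 0.77`, both requiring adjusted `p < 0.05`.
#' The aging condition uses the age coefficient: up if `coef >= 0.005`,
#' down if `coef <= -0.005`, both requiring `FDR < 0.01` (the magnitude
#' threshold corresponds to roughly a 10% fold change). Effect boundaries
#' are inclusive; significance cutoffs are strict.
#'
#' @param table DE data.frame (see [read_de_table()]).
#' @param condition `"neurotransmission"` or `"aging"`.
#' @param cell `"neuron"` or `"astrocyte"`.
#' @return list with `up` and `down` gene sets.
#' @export
filter_de_genes <- function(table, condition = c("neurotransmission", "aging"),
                            cell = c("neuron", "astrocyte")) {
  condition <- match.arg(condition)
  cell <- match.arg(cell)
  validate_de_table(table)
  rows <- table[table$condition == condition & table$cell == cell, ]
  if (condition == "neurotransmission") {
    sig <- rows$significance < 0.05
    up <- rows$gene_id[sig & rows$effect >= 1.3]
    down <- rows$gene_id[sig & rows$effect <= 0.77]
  } else {
    sig <- rows$significance < 0.01
    up <- rows$gene_id[sig & rows$effect >= 0.005]
    down <- rows$gene_id[sig & rows$effect <= -0.005]
  }
  list(up = sort(unique(up)), down = sort(unique(down)))
}

#' Derive differential hub genes
#'
#' Intersects the hub gene set with the filtered differential-expression sets
#' in every cell x condition stratum, tagging each differential hub gene with
#' its direction.
#'
#' @param hub character vector of hub genes.
#' @param de_table DE data.frame covering the strata of interest.
#' @param conditions,cells strata to evaluate.
#' @return `DHGResult`: list with `hub_genes` and `strata`, a named list
#'   (`cell.condition`) of data.frames with columns `gene`, `direction`.
#' @export
derive_dhg <- function(hub, de_table,
                       conditions = c("neurotransmission", "aging"),
                       cells = c("neuron", "astrocyte")) {
  strata <- list()
  for (cell in cells) {
    for (cond in conditions) {
      if (!any(de_table$cell == cell & de_table$condition == cond)) next
      f <- filter_de_genes(de_table, cond, cell)
      g_up <- intersect(hub, f$up)
      g_dn <- intersect(hub, f$down)
      strata[[paste(cell, cond, sep = ".")]] <- data.frame(
        gene = c(g_up, g_dn),
        direction = rep(c("up", "down"), c(length(g_up), length(g_dn))),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(hub_genes = sort(unique(hub)), strata = strata),
            class = "DHGResult")
}

#' @export
print.DHGResult <- function(x, ...) {
  cat(sprintf("DHGResult: %d hub genes\n", length(x$hub_genes)))
  for (nm in names(x$strata)) {
    cat(sprintf("  %-28s %d DHG (%d up, %d down)\n", nm,
                nrow(x$strata[[nm]]),
                sum(x$strata[[nm]]$direction == "up"),
                sum(x$strata[[nm]]$direction == "down")))
  }
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set with at least `min_overlap` genes in common with the
#' query, computes the hypergeometric upper-tail probability of drawing at
#' least that overlap in `|query|` draws (without replacement) from the
#' background, and adjusts across tested sets with Benjamini-Hochberg.
#'
#' @param query character vector of genes (must be contained in
#'   `background`).
#' @param background character vector: the gene universe.
#' @param collection named list of gene sets (intersected with the
#'   background before testing).
#' @param min_overlap minimum query/set overlap for a set to be tested
#'   (default 2).
#' @return data.frame with columns `set_name`, `overlap_count`, `set_size`,
#'   `query_size`, `background_size`, `p_value`, `fdr`, sorted by p.
#' @export
enrich_gene_sets <- function(query, background, collection, min_overlap = 2) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background)) {
    stop("query genes outside the background: ",
         paste(setdiff(query, background), collapse = ", "))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], background)
    k <- length(intersect(set, query))
    if (k < min_overlap) return(NULL)
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(set),
               query_size = n, background_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set_name = character(0), overlap_count = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      background_size = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
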