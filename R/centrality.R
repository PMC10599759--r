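#' Reaction projection of the stoichiometric matrix
#'
#' Builds the undirected reaction graph: nodes are reactions, and two
#' reactions are joined when they share at least one metabolite (with nonzero
#' stoichiometric coefficient in both columns) that is not excluded. The edge
#' weight counts the shared metabolites. Currency metabolites (ATP/ADP and the
#' like) are typically excluded so the projection reflects the substrate
#' backbone rather than one large cofactor clique.
#'
#' @param model a [metabolic_model()].
#' @param exclude_metabolites metabolite ids dropped before projecting.
#' @return an [igraph::graph] with vertex attributes `name` and `cell_label`,
#'   edge attribute `weight`, and graph attribute `excluded`.
#' @export
project_reactions <- function(model, exclude_metabolites = character(0)) {
  validate_model(model)
  keep <- !(model$metabolite_ids %in% exclude_metabolites)
  A <- (model$S[keep, , drop = FALSE] != 0) * 1
  W <- crossprod(A)           # shared-metabolite counts
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$cell_label <- model$cell_label[match(igraph::V(g)$name,
                                                    model$reaction_ids)]
  g <- igraph::set_graph_attr(g, "excluded",
                              model$metabolite_ids[!keep])
  g
}

#' Node centrality scores
#'
#' Computes one of the supported centrality metrics on an undirected graph
#' (edge weights are ignored; the projection is treated as unweighted):
#' \describe{
#'   \item{eigenvector}{principal eigenvector of the adjacency matrix,
#'     computed per connected component by deterministic power iteration
#'     (uniform start, tolerance 1e-10) and max-normalized within each
#'     component. Singleton components score 0.}
#'   \item{closeness}{`(r - 1)/sum(d)` over the `r` reachable vertices,
#'     scaled by `(r - 1)/(N - 1)` (Wasserman-Faust correction for
#'     disconnected graphs). Isolated vertices score 0.}
#'   \item{information}{Stephenson-Zelen current-flow information
#'     centrality, `1/(C_ii + (T - 2R_i)/n)` with `C = (L + J)^{-1}`, per
#'     connected component (the common reciprocal-total-resistance variant
#'     equals this divided by the component size); singletons score 0.}
#'   \item{betweenness}{shortest-path betweenness (used only as the optional
#'     fourth metric of the clustering QC, not in the ACC aggregation).}
#' }
#'
#' @param graph an igraph graph (e.g. from [project_reactions()]).
#' @param metric one of `"eigenvector"`, `"closeness"`, `"information"`,
#'   `"betweenness"`.
#' @return named numeric vector of scores.
#' @export
node_centrality <- function(graph,
                            metric = c("eigenvector", "closeness",
                                       "information", "betweenness")) {
  metric <- match.arg(metric)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  score <- switch(metric,
    eigenvector = eigenvector_by_component(graph),
    closeness = closeness_wf(graph),
    information = information_centrality(graph),
    betweenness = igraph::betweenness(graph, directed = FALSE, weights = NA)
  )
  stats::setNames(as.numeric(score), ids)
}

eigenvector_by_component <- function(graph) {
  n <- igraph::vcount(graph)
  comp <- igraph::components(graph)$membership
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  A <- (A != 0) * 1
  out <- numeric(n)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) == 1L || sum(A[idx, idx]) == 0) next  # singleton: 0
    out[idx] <- power_iteration(A[idx, idx, drop = FALSE])
  }
  out
}

# deterministic power iteration; returns the max-normalized principal vector
power_iteration <- function(A, tol = 1e-10, max_iter = 1e5) {
  x <- rep(1 / sqrt(nrow(A)), nrow(A))
  # shift guarantees convergence on bipartite components
  shift <- 1e-3
  for (i in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + shift * x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(rep(0, nrow(A)))
    y <- y / ny
    if (max(abs(y - x)) < tol) { x <- y; break }
    x <- y
  }
  x / max(x)
}

closeness_wf <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 1L) return(0)
  D <- igraph::distances(graph, weights = NA)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, numeric(1))
}

information_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  comp <- igraph::components(graph)$membership
  A <- (igraph::as_adjacency_matrix(graph, sparse = FALSE) != 0) * 1
  out <- numeric(n)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    nk <- length(idx)
    if (nk == 1L) next  # singleton: 0
    Ak <- A[idx, idx, drop = FALSE]
    L <- diag(rowSums(Ak)) - Ak
    C <- solve(L + matrix(1, nk, nk))
    Tr <- sum(diag(C)); R <- rowSums(C)
    out[idx] <- 1 / (diag(C) + (Tr - 2 * R) / nk)
  }
  out
}

#' Induced centrality of every node with respect to the sensitivity set
#'
#' The basal cohesiveness of the sensitivity set `s` is the mean of the
#' chosen centrality over its members. For each node `x` the graph is
#' rebuilt without `x`, the centrality of the surviving members of `s` is
#' recomputed and averaged, and the induced centrality is the log2 fold
#' change `I_c(x) = log2(C_basal / C_-x)`. When `x` itself belongs to `s`,
#' both means are taken over `s \ {x}`. Means are floored at `1e-12` before
#' the ratio (with a warning) so a collapse to zero remains finite.
#'
#' @param graph an igraph graph.
#' @param s character vector of sensitivity-set node names (subset of the
#'   graph's nodes).
#' @param metric centrality metric, as in [node_centrality()].
#' @return named numeric vector `I_c(x)` over all nodes.
#' @export
induced_centrality <- function(graph, s, metric = "eigenvector") {
  nodes <- igraph::V(graph)$name
  if (!length(s)) stop("sensitivity set is empty")
  if (!all(s %in% nodes)) {
    stop("sensitivity set members missing from graph: ",
         paste(setdiff(s, nodes), collapse = ", "))
  }
  eps <- 1e-12
  floor_mean <- function(x) {
    if (!length(x)) return(NA_real_)
    m <- mean(x)
    if (m < eps) {
      warning("mean centrality floored at 1e-12")
      m <- eps
    }
    m
  }
  base_scores <- node_centrality(graph, metric)
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (x in nodes) {
    sx <- setdiff(s, x)
    if (!length(sx)) { out[x] <- 0; next }  # nothing left to compare
    c_basal <- floor_mean(base_scores[sx])
    g2 <- igraph::delete_vertices(graph, x)
    c_minus <- floor_mean(node_centrality(g2, metric)[sx])
    out[x] <- log2(c_basal / c_minus)
  }
  out
}

#' Aggregate induced centralities into the Absolute Centrality Contribution
#'
#' Each induced-centrality column is normalized with
#' [pseudo_log_normalize()]; the normalized eigenvector contribution is the
#' probability term `P_s`, the sum of the normalized closeness and
#' information contributions is the cost term `C_s`, and
#' `ACC = sqrt(P_s^2 + C_s^2)` (range `[0, sqrt(5)]`).
#'
#' @param induced data.frame or matrix with columns `eigenvector`,
#'   `closeness`, `information` of induced centralities per node (rownames or
#'   column `reaction_id` identify the nodes).
#' @param cell_labels per-node cell labels (same order).
#' @param q percentile for the central flag (default 90).
#' @return `CentralityTable` data.frame with columns `reaction_id`,
#'   `cell_label`, `i_eig`, `i_clo`, `i_inf`, `p_s`, `c_s`, `acc`,
#'   `is_central`.
#' @export
aggregate_acc <- function(induced, cell_labels, q = 90) {
  need <- c("eigenvector", "closeness", "information")
  induced <- as.data.frame(induced)
  miss <- setdiff(need, names(induced))
  if (length(miss)) stop("missing metric column(s): ",
                         paste(miss, collapse = ", "))
  ids <- if (!is.null(induced$reaction_id)) induced$reaction_id else
    rownames(induced)
  p_s <- pseudo_log_normalize(induced$eigenvector)
  c_s <- pseudo_log_normalize(induced$closeness) +
    pseudo_log_normalize(induced$information)
  acc <- sqrt(p_s^2 + c_s^2)
  sel <- select_top_percentile(acc, cell_labels, ids, q)
  data.frame(reaction_id = ids, cell_label = cell_labels,
             i_eig = induced$eigenvector, i_clo = induced$closeness,
             i_inf = induced$information,
             p_s = p_s, c_s = c_s, acc = acc,
             is_central = ids %in% sel, stringsAsFactors = FALSE)
}

#' Select central reactions from a centrality table
#'
#' Per-cell top-percentile selection on the ACC column (the last tenth
#' percentile per cell at the default `q = 90`).
#'
#' @param table a [aggregate_acc()] result.
#' @param q percentile (default 90); `q = 0` selects every node.
#' @return character vector of central reaction ids.
#' @export
select_central <- function(table, q = 90) {
  select_top_percentile(table$acc, table$cell_label, table$reaction_id, q)
}

#' Correlation / clustering / PCA quality control of nodal contributions
#'
#' Each reaction is treated as a variable whose samples are its induced
#' centralities under the different metrics. Computes the reaction-by-reaction
#' Pearson correlation matrix, complete-linkage hierarchical clustering on
#' Euclidean distances between correlation rows, a standard PCA of the
#' correlation matrix, and a separation score: the fraction of reactions
#' whose 2-cluster assignment matches their cell label (maximized over the
#' two label permutations; exchange-labeled reactions are left out of the
#' score).
#'
#' @param induced matrix/data.frame of induced centralities, nodes x metrics
#'   (typically eigenvector, closeness, information and betweenness).
#' @param cell_labels per-node cell labels.
#' @return list with `correlation`, `hclust`, `pca` (a `prcomp`),
#'   `cluster` (2-cluster assignment) and `separation`.
#' @export
correlation_clustering <- function(induced, cell_labels) {
  M <- as.matrix(as.data.frame(induced)[,
         sapply(as.data.frame(induced), is.numeric), drop = FALSE])
  if (nrow(M) < 2L) stop("need at least two nodes")
  zero_var <- apply(M, 1, stats::sd) == 0
  R <- suppressWarnings(stats::cor(t(M)))
  if (any(zero_var)) {
    warning("zero-variance node(s); their correlations set to 0")
    R[zero_var, ] <- 0; R[, zero_var] <- 0
  }
  diag(R) <- 1
  hc <- stats::hclust(stats::dist(R, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = 2)
  pca <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  cellular <- cell_labels %in% c("neuron", "astrocyte")
  truth <- as.integer(factor(cell_labels[cellular],
                             levels = c("neuron", "astrocyte")))
  hit1 <- mean(cl[cellular] == truth)
  hit2 <- mean(cl[cellular] == 3L - truth)
  list(correlation = R, hclust = hc, pca = pca, cluster = cl,
       separation = max(hit1, hit2))
}
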