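toy_graph <- function(edges, n = NULL) {
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::V(g)$name <- letters[seq_len(igraph::vcount(g))]
  g
}

test_that("reaction projection equals the boolean cross-product oracle", {
  model <- generate_toy_network(synthetic_spec(seed = 1))
  excl <- currency_metabolites(model)
  g <- project_reactions(model, excl)
  A <- (model$S[!(model$metabolite_ids %in% excl), , drop = FALSE] != 0) * 1
  W <- crossprod(A); diag(W) <- 0
  got <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(got[model$reaction_ids, model$reaction_ids],
               unname(W[model$reaction_ids, model$reaction_ids]) +
                 0 * got[model$reaction_ids, model$reaction_ids],
               tolerance = 0)
  expect_true(all(diag(got) == 0))
  expect_identical(sort(igraph::V(g)$name), sort(model$reaction_ids))
})

test_that("shared metabolites define edges; exclusion removes the clique", {
  m <- metabolic_model(c("met", "cur"), c("R1", "R2", "R3"),
                       rbind(c(1, -1, 0), c(1, 1, 1)),
                       rep(0, 3), rep(1, 3))
  g_all <- project_reactions(m)
  expect_equal(igraph::ecount(g_all), 3)   # currency welds a triangle
  g_ex <- project_reactions(m, exclude_metabolites = "cur")
  expect_equal(igraph::ecount(g_ex), 1)
  edge <- igraph::as_ids(igraph::E(g_ex))
  expect_identical(edge, "R1|R2")
})

test_that("eigenvector centrality: star closed form, max-normalized", {
  g <- toy_graph(c(1,2, 1,3, 1,4))
  ev <- node_centrality(g, "eigenvector")
  expect_equal(unname(ev), c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-8)
})

test_that("closeness uses the Wasserman-Faust disconnected scaling", {
  g <- toy_graph(c(1,2, 2,3))
  clo <- node_centrality(g, "closeness")
  expect_equal(unname(clo), c(2/3, 1, 2/3), tolerance = 1e-12)
  # disconnected: component of 2 plus an isolate, N = 3
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE) + igraph::vertices(3)
  igraph::V(g2)$name <- c("a", "b", "c")
  clo2 <- node_centrality(g2, "closeness")
  expect_equal(unname(clo2), c(0.5, 0.5, 0), tolerance = 1e-12)
})

test_that("information centrality matches current-flow reference values", {
  star <- toy_graph(c(1,2, 1,3, 1,4))
  inf_star <- node_centrality(star, "information")
  # Stephenson-Zelen values; the reciprocal-total-resistance variant is
  # these divided by the component size n = 4
  expect_equal(unname(inf_star), c(4/3, 0.8, 0.8, 0.8), tolerance = 1e-9)
  p4 <- toy_graph(c(1,2, 2,3, 3,4))
  expect_equal(unname(node_centrality(p4, "information")),
               4 * c(1/6, 1/4, 1/4, 1/6), tolerance = 1e-9)
  k3 <- toy_graph(c(1,2, 2,3, 3,1))
  inf3 <- node_centrality(k3, "information")
  expect_equal(max(inf3) - min(inf3), 0, tolerance = 1e-12)
})

test_that("induced centrality reproduces the hand-worked path example", {
  g <- toy_graph(c(1,2, 2,3, 3,4))   # a-b-c-d
  ic <- induced_centrality(g, s = "b", metric = "closeness")
  # C_basal = closeness(b) on P4 = 3/4; removing d leaves P3 where b has 1.0
  expect_equal(unname(ic["d"]), log2(0.75 / 1), tolerance = 1e-12)
  # removing an isolated bystander only changes the graph-size scaling:
  # closeness(b) is (3/4)*(3/4) with the isolate present and 3/4 without
  g2 <- g + igraph::vertices("z")
  ic2 <- induced_centrality(g2, s = "b", metric = "closeness")
  expect_equal(unname(ic2["z"]), log2(0.5625 / 0.75), tolerance = 1e-12)
})

test_that("induced centrality equals the from-scratch removal oracle", {
  set.seed(11)
  for (rep in 1:3) {
    g <- igraph::sample_gnp(18, 0.18)
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
    s <- sample(igraph::V(g)$name, 4)
    for (metric in c("eigenvector", "closeness", "information")) {
      got <- suppressWarnings(induced_centrality(g, s, metric))
      want <- suppressWarnings(naive_induced(g, s, metric))
      expect_equal(got, want, tolerance = 1e-10,
                   label = paste(metric, "rep", rep))
    }
  }
  # synthetic-scale graph, one metric, exact agreement
  model <- generate_toy_network(synthetic_spec(seed = 3))
  g <- project_reactions(model, currency_metabolites(model))
  sol <- solve_fba(model)
  s <- extract_sensitivity_set(sol)$s
  expect_equal(suppressWarnings(induced_centrality(g, s, "closeness")),
               suppressWarnings(naive_induced(g, s, "closeness")),
               tolerance = 1e-10)
})

test_that("removing a member of a singleton sensitivity set is flagged zero", {
  g <- toy_graph(c(1,2, 2,3))
  ic <- suppressWarnings(induced_centrality(g, s = "b", metric = "closeness"))
  expect_identical(unname(ic["b"]), 0)
})

test_that("ACC aggregation: arithmetic, bounds and degenerate input", {
  zero <- data.frame(eigenvector = rep(0, 4), closeness = rep(0, 4),
                     information = rep(0, 4),
                     reaction_id = paste0("r", 1:4))
  out <- aggregate_acc(zero, rep(c("neuron", "astrocyte"), 2))
  expect_true(all(out$acc == 0))
  set.seed(3)
  ind <- data.frame(eigenvector = stats::rnorm(30),
                    closeness = stats::rnorm(30),
                    information = stats::rnorm(30),
                    reaction_id = paste0("r", 1:30))
  out2 <- aggregate_acc(ind, rep(c("neuron", "astrocyte"), 15))
  expect_equal(out2$acc, sqrt(out2$p_s^2 + out2$c_s^2), tolerance = 1e-12)
  expect_equal(out2$c_s, pseudo_log_normalize(ind$closeness) +
                 pseudo_log_normalize(ind$information), tolerance = 1e-12)
  expect_true(all(out2$acc <= sqrt(5) + 1e-12))
  expect_error(aggregate_acc(ind[, -1], rep("neuron", 30)), "eigenvector")
})

test_that("central selection honors the per-cell percentile and q = 0", {
  tab <- data.frame(reaction_id = paste0("r", 1:20),
                    cell_label = rep(c("neuron", "astrocyte"), each = 10),
                    acc = c(1:10, 1:10))
  expect_setequal(select_central(tab, q = 90), c("r10", "r20"))
  expect_length(select_central(tab, q = 0), 20)
})

test_that("correlation clustering recovers a planted anti-correlated split", {
  v <- c(1.2, -0.4, 0.8, -1.5)
  M <- rbind(matrix(rep(v, 5), nrow = 5, byrow = TRUE) +
               matrix(stats::rnorm(20, sd = 0.01), 5),
             matrix(rep(-v, 5), nrow = 5, byrow = TRUE) +
               matrix(stats::rnorm(20, sd = 0.01), 5))
  labs <- rep(c("neuron", "astrocyte"), each = 5)
  out <- correlation_clustering(M, labs)
  expect_equal(out$separation, 1.0)
  expect_true(all(abs(out$correlation[1:5, 1:5]) > 0.9))
  expect_true(all(out$correlation[1:5, 6:10] < -0.9))
  expect_equal(out$correlation, t(out$correlation), tolerance = 1e-12)
  expect_equal(unname(diag(out$correlation)), rep(1, 10))
  # zero-variance node handled with a warning
  M2 <- rbind(M, 0)
  expect_warning(correlation_clustering(M2, c(labs, "neuron")),
                 "zero-variance")
})
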