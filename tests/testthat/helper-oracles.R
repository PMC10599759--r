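# Shared fixtures and independent oracles for the test suite.

# three-reaction chain: uptake (capped) -> convert -> export, objective on export
chain_model <- function(cap = 10) {
  metabolic_model(
    metabolite_ids = c("m1", "m2"),
    reaction_ids = c("uptake", "convert", "export"),
    S = rbind(c(1, -1, 0), c(0, 1, -1)),
    lower_bounds = c(0, 0, 0), upper_bounds = c(cap, 100, 100),
    objective_coefficients = c(0, 0, 1)
  )
}

# random generic LP model (continuous data => unique optimum/dual a.s.)
random_lp_model <- function(seed, n_rxn = NULL, n_met = NULL) {
  set.seed(seed)
  n <- if (is.null(n_rxn)) sample(3:8, 1) else n_rxn
  m <- if (is.null(n_met)) sample(2:(n - 1), 1) else n_met
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    rows <- sample(m, min(m, sample(1:2, 1)))
    S[rows, j] <- round(stats::runif(length(rows), -2, 2), 3)
  }
  lb <- round(stats::runif(n, -4, 0), 3)
  ub <- lb + round(stats::runif(n, 0.5, 6), 3)
  cc <- round(stats::runif(n, -1, 1), 3)
  metabolic_model(paste0("m", seq_len(m)), paste0("r", seq_len(n)), S,
                  lb, ub, cc)
}

# brute-force LP oracle: enumerate candidate vertices (basic feasible points)
enumerate_lp_optimum <- function(model, tol = 1e-9) {
  S <- model$S; l <- model$lower_bounds; u <- model$upper_bounds
  cc <- model$objective_coefficients
  n <- ncol(S); m <- nrow(S)
  best <- -Inf; best_v <- NULL
  for (k in 0:min(n, m)) {
    for (basic in if (k == 0) list(integer(0)) else
         asplit(utils::combn(n, k), 2)) {
      basic <- as.integer(basic)
      nonbasic <- setdiff(seq_len(n), basic)
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nonbasic)))
      for (g in seq_len(max(1, nrow(grid)))) {
        v <- numeric(n)
        at_up <- if (length(nonbasic)) unlist(grid[g, ]) else logical(0)
        v[nonbasic] <- ifelse(at_up, u[nonbasic], l[nonbasic])
        if (k > 0) {
          A <- S[, basic, drop = FALSE]
          rhs <- -S[, nonbasic, drop = FALSE] %*% v[nonbasic]
          sol <- tryCatch(qr.solve(A, rhs, tol = 1e-10),
                          error = function(e) NULL)
          if (is.null(sol)) next
          v[basic] <- sol
        }
        if (max(abs(S %*% v)) > 1e-7) next
        if (any(v < l - tol) || any(v > u + tol)) next
        z <- sum(cc * v)
        if (z > best) { best <- z; best_v <- v }
      }
    }
  }
  list(z = best, v = best_v)
}

# finite-difference reduced cost at an active bound: (z(b + eps) - z(b)) / eps
fd_reduced_cost <- function(model, j, eps = 1e-6) {
  sol <- solve_fba(model)
  v <- sol$v[j]
  m2 <- model
  scale <- max(1, abs(model$upper_bounds[j]), abs(model$lower_bounds[j]))
  h <- eps * scale
  if (abs(v - model$upper_bounds[j]) < 1e-7 * scale) {
    m2$upper_bounds[j] <- m2$upper_bounds[j] + h
  } else if (abs(v - model$lower_bounds[j]) < 1e-7 * scale) {
    m2$lower_bounds[j] <- m2$lower_bounds[j] - h
    h <- -h
  } else {
    return(0)  # interior flux: objective insensitive
  }
  (solve_fba(m2)$z - sol$z) / h
}

# from-scratch node-removal oracle built on the raw adjacency matrix
naive_induced <- function(graph, s, metric) {
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  nodes <- rownames(A)
  rebuild <- function(keep) {
    igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                        mode = "undirected", weighted = TRUE)
  }
  out <- stats::setNames(numeric(length(nodes)), nodes)
  base <- node_centrality(rebuild(nodes), metric)
  for (x in nodes) {
    sx <- setdiff(s, x)
    if (!length(sx)) { out[x] <- 0; next }
    cb <- max(mean(base[sx]), 1e-12)
    cm <- max(mean(node_centrality(rebuild(setdiff(nodes, x)), metric)[sx]),
              1e-12)
    out[x] <- log2(cb / cm)
  }
  out
}

# hypergeometric upper tail by complete enumeration of all draws
enumerate_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # successes are items 1..K
  mean(hits >= k)
}
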