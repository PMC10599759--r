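test_that("hub genes union GPRs with per-gene provenance", {
  m <- metabolic_model(
    c("x"), c("R1", "R2", "R3"), matrix(c(1, -1, 0), 1),
    rep(0, 3), rep(1, 3),
    gpr = c("g1 and g2", "g2 or g3", "")
  )
  out <- hub_genes(m, optimal_rxns = "R1", central_rxns = c("R2", "R3"))
  expect_setequal(out$genes, c("g1", "g2", "g3"))
  g2src <- sort(out$provenance$source[out$provenance$gene == "g2"])
  expect_identical(g2src, c("central", "optimal"))
  # empty GPR contributes nothing; empty inputs give the empty set
  expect_length(hub_genes(m, character(0), character(0))$genes, 0)
  expect_error(hub_genes(m, "nope", character(0)), "unknown")
  # provenance re-expands to cover exactly the hub gene set
  re <- unique(unlist(lapply(unique(out$provenance$reaction), function(r) {
    parse_gpr(m$gpr[match(r, m$reaction_ids)])
  })))
  expect_setequal(re, out$genes)
})

test_that("gene id mapping handles lookups, identity and one-to-many", {
  map <- data.frame(source = c("h1", "h3", "h3"),
                    target = c("m1", "m3a", "m3b"))
  out <- map_gene_ids(c("h1", "h2"), map)
  expect_identical(out$mapped, "m1")
  expect_identical(out$unmapped, "h2")
  idm <- data.frame(source = c("a", "b"), target = c("a", "b"))
  expect_setequal(map_gene_ids(c("a", "b"), idm)$mapped, c("a", "b"))
  expect_setequal(map_gene_ids("h3", map)$mapped, c("m3a", "m3b"))
  expect_warning(map_gene_ids("x", map[0, ]), "empty mapping")
})

test_that("DE filters apply the published thresholds at their boundaries", {
  de <- data.frame(
    gene_id = paste0("g", 1:6),
    effect = c(1.3, 1.2, 0.77, 0.8, 1.3, 0.5),
    significance = c(0.04, 0.001, 0.04, 0.01, 0.05, 0.049),
    cell = "neuron", condition = "neurotransmission")
  f <- filter_de_genes(de, "neurotransmission", "neuron")
  expect_setequal(f$up, "g1")          # FC = 1.3 inclusive, padj < 0.05
  expect_setequal(f$down, c("g3", "g6"))
  expect_false("g2" %in% c(f$up, f$down))   # effect below cutoff
  expect_false("g5" %in% f$up)              # padj = 0.05 strict

  age <- data.frame(
    gene_id = paste0("a", 1:5),
    effect = c(0.005, -0.005, -0.006, 0.004, 0.02),
    significance = c(0.009, 0.009, 0.02, 0.001, 0.01),
    cell = "astrocyte", condition = "aging")
  fa <- filter_de_genes(age, "aging", "astrocyte")
  expect_setequal(fa$up, "a1")          # boundary inclusive on the effect
  expect_setequal(fa$down, "a2")
  expect_false("a3" %in% fa$down)       # FDR fails (strict 0.01)
  expect_false("a5" %in% fa$up)         # FDR = 0.01 strict
  expect_error(filter_de_genes(de[, -2], "neurotransmission", "neuron"),
               "missing")
})

test_that("differential hub genes are the tagged hub/DE intersection", {
  de <- data.frame(
    gene_id = c("g1", "g2", "g9", "g3"),
    effect = c(2, 0.5, 1.8, 1.0),
    significance = c(0.01, 0.01, 0.01, 0.01),
    cell = "neuron", condition = "neurotransmission")
  out <- derive_dhg(c("g1", "g2"), de)
  strat <- out$strata[["neuron.neurotransmission"]]
  expect_setequal(strat$gene, c("g1", "g2"))
  expect_identical(strat$direction[strat$gene == "g1"], "up")
  expect_identical(strat$direction[strat$gene == "g2"], "down")
  # invariants: dhg within hub and within the DE sets
  expect_true(all(strat$gene %in% out$hub_genes))
  empty <- derive_dhg(character(0), de)
  expect_identical(nrow(empty$strata[["neuron.neurotransmission"]]), 0L)
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  # derived example: background 20, set 5, query 5, overlap 4
  background <- paste0("g", 1:20)
  query <- paste0("g", 1:5)
  coll <- list(hit = c(paste0("g", 1:4), "g20"),
               tiny = c("g1", "g19"))
  enr <- enrich_gene_sets(query, background, coll, min_overlap = 2)
  expect_equal(enr$p_value[enr$set_name == "hit"], 76 / 15504,
               tolerance = 1e-12)
  # brute-force enumeration over all C(20,5) draws
  expect_equal(enr$p_value[enr$set_name == "hit"],
               enumerate_hyper_tail(20, 5, 5, 4), tolerance = 1e-12)
  # random cases, N <= 20
  set.seed(9)
  for (i in 1:5) {
    N <- sample(8:20, 1); K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    bg <- paste0("x", 1:N)
    q <- sample(bg, n); st <- list(s = bg[1:K])
    e <- enrich_gene_sets(q, bg, st, min_overlap = 0)
    k <- length(intersect(q, st$s))
    if (nrow(e)) {
      expect_equal(e$p_value, enumerate_hyper_tail(N, K, n, k),
                   tolerance = 1e-10, label = paste("case", i))
    }
  }
})

test_that("enrichment respects min_overlap, containment and saturation", {
  bg <- paste0("g", 1:20)
  q <- paste0("g", 1:5)
  low <- enrich_gene_sets(q, bg, list(one = c("g1", "g18")), min_overlap = 2)
  expect_identical(nrow(low), 0L)   # overlap 1 with min 2: not tested
  sat <- enrich_gene_sets(bg, bg, list(all = bg), min_overlap = 2)
  expect_equal(sat$p_value, 1, tolerance = 1e-12)
  expect_error(enrich_gene_sets(c("g1", "zz"), bg, list(a = q)), "outside")
  # BH adjustment is ordering-consistent
  set.seed(1)
  coll <- lapply(1:6, function(i) sample(bg, 6))
  names(coll) <- paste0("s", 1:6)
  e <- enrich_gene_sets(q, bg, coll, min_overlap = 1)
  expect_true(all(diff(e$p_value) >= 0))
  expect_true(all(e$fdr >= e$p_value - 1e-12))
})

test_that("the full synthetic pipeline recovers planted DHGs exactly", {
  spec <- synthetic_spec(seed = 11)
  model <- generate_toy_network(spec)
  de <- generate_de_tables(model, spec)
  sets <- generate_pathway_sets(model, spec)
  mapping <- generate_mapping(model, spec)
  res <- run_hub_pipeline(model, de, sets, mapping = mapping)
  planted <- default_planted_de(spec)
  for (key in names(planted)) {
    truth <- sort(unique(unlist(planted[[key]])))
    got <- sort(res$dhg$strata[[key]]$gene)
    expect_identical(got, truth, label = key)
  }
  expect_lt(res$enrichment$fdr[res$enrichment$set_name == "planted_pathway"],
            0.05)
})
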