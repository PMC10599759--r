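#' Specification for the synthetic two-cell benchmark
#'
#' Describes the synthetic neuron-astrocyte model and the planted ground
#' truth used to validate the whole pipeline: the number of reactions per
#' cell, the metabolites exchanged between the cells and the medium, the
#' reactions intended to come out as hubs, the genes planted as
#' differentially expressed per cell x condition stratum, and the seed that
#' fully determines the output.
#'
#' @param n_core_reactions_per_cell total reactions per cell, core skeleton
#'   plus hub plus topological filler (default 30; minimum 14).
#' @param exchanged_metabolites subset of the supported exchanged species
#'   (`lactate`, `glutamate`, `glutamine`, `sodium`, `glucose`, `oxygen`).
#' @param planted_hub_reactions reaction ids wired as high-degree connectors
#'   (default one per cell).
#' @param planted_de_genes optional named list
#'   (`"<cell>.<condition>" -> list(up =, down =)`); when `NULL`, a default
#'   drawing from the sodium pump, the glucose transporters and the hub
#'   reactions is used.
#' @param seed integer seed; generation is a pure function of it.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_core_reactions_per_cell = 30,
                           exchanged_metabolites = c("lactate", "glutamate",
                                                     "glutamine", "sodium",
                                                     "glucose", "oxygen"),
                           planted_hub_reactions = c("HUB_n", "HUB_a"),
                           planted_de_genes = NULL,
                           seed = 1L) {
  supported <- c("lactate", "glutamate", "glutamine", "sodium", "glucose",
                 "oxygen")
  extra <- setdiff(exchanged_metabolites, supported)
  if (length(extra)) {
    stop("unsupported exchanged metabolite(s): ", paste(extra, collapse = ", "))
  }
  if (n_core_reactions_per_cell < 14) {
    stop("need at least 14 reactions per cell for the core skeleton")
  }
  structure(list(n_core_reactions_per_cell = n_core_reactions_per_cell,
                 exchanged_metabolites = exchanged_metabolites,
                 planted_hub_reactions = planted_hub_reactions,
                 planted_de_genes = planted_de_genes,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

with_spec_seed <- function(spec, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed + offset)
  force(code)
}

#' Generate a feasible synthetic two-cell metabolic model
#'
#' Builds a neuron and an astrocyte, each with a lumped
#' glycolysis/pyruvate/TCA-oxphos/ATP skeleton (31 ATP per fully oxidized
#' glucose: 2 glycolytic, 14.5 per pyruvate), connected by the
#' astrocyte-neuron lactate shuttle (astrocytic lactate export, neuronal
#' lactate import) and the glutamate-glutamine cycle (neuronal vesicular
#' glutamate export, astrocytic glutamine return), plus a neuronal
#' Na/K-ATPase extruding 3 Na per ATP fed by a sodium leak. The
#' neurotransmission objective places weight 1 on exactly the five coupled
#' flux carriers (sodium pump, both lactate-shuttle transporters, vesicular
#' glutamate export, glutamine export). Default bounds install the measured
#' constants of [fba_constants()]: the stimulated neuronal glycolytic cap,
#' the astrocytic oxygen uptake and the fixed housekeeping ATP drain.
#'
#' Each planted hub reaction is a high-degree salvage connector touching
#' many core metabolites of its cell (the neuronal hub additionally bridges
#' extracellular lactate, joining the two cells), so hub removal reshapes
#' the reaction graph far more than any other single removal. Topological
#' filler gives the two cells opposite redundancy structure -- an isozyme
#' mesh around the neuronal bottlenecks, pendant byproduct-drain chains on
#' the astrocytic core -- which makes their reactions' induced-centrality
#' profiles oppositely signed, the signature the clustering QC probes.
#' Every internal reaction carries a non-empty GPR over synthetic gene ids.
#'
#' @param spec a [synthetic_spec()].
#' @return a [metabolic_model()].
#' @export
generate_toy_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  k <- fba_constants()
  rxn <- list()
  add <- function(id, mets, lb, ub, obj = 0, gpr = "") {
    rxn[[id]] <<- list(mets = mets, lb = lb, ub = ub, obj = obj, gpr = gpr)
  }
  g1 <- function(id) sprintf("g_%s_1", tolower(id))
  g2 <- function(id) sprintf("g_%s_1 and g_%s_2", tolower(id), tolower(id))
  g3 <- function(id) sprintf("g_%s_1 or g_%s_2 or g_%s_3",
                             tolower(id), tolower(id), tolower(id))

  ex <- spec$exchanged_metabolites
  # medium exchanges (negative flux = uptake)
  if ("glucose" %in% ex) add("EX_glc", c(glc_e = -1), -100, 0)
  if ("oxygen" %in% ex) add("EX_o2", c(o2_e = -1), -100, 0)
  if ("lactate" %in% ex) add("EX_lac", c(lac_e = -1), 0, 100)
  if ("sodium" %in% ex) add("EX_na", c(na_e = -1), -1000, 1000)

  for (cell in c("n", "a")) {
    s <- function(m) paste0(m, "_", cell)
    id <- function(r) paste0(r, "_", cell)
    glc_cap <- if (cell == "n") k$stimulated_glycolysis else 10
    add(id("GLCt"), stats::setNames(c(-1, 1), c("glc_e", s("glc"))),
        0, glc_cap, gpr = g1(id("GLCt")))
    add(id("HEX"), stats::setNames(c(-1, -2, -2, 2, 2),
        c(s("glc"), s("adp"), s("pi"), s("pyr"), s("atp"))),
        0, 100, gpr = g2(id("HEX")))
    add(id("LDH"), stats::setNames(c(-1, 1), c(s("pyr"), s("lac"))),
        -100, 100, gpr = g2(id("LDH")))
    add(id("OXPHOS"), stats::setNames(c(-1, -2.5, -14.5, -14.5, 14.5),
        c(s("pyr"), s("o2"), s("adp"), s("pi"), s("atp"))),
        0, 100, gpr = g2(id("OXPHOS")))
    o2_cap <- if (cell == "n") 50 else k$astro_o2_uptake
    add(id("O2t"), stats::setNames(c(-1, 1), c("o2_e", s("o2"))),
        0, o2_cap, gpr = g1(id("O2t")))
    if (cell == "n") {
      add("ATPM_n", c(atp_n = -1, adp_n = 1, pi_n = 1),
          k$housekeeping_atp, k$housekeeping_atp, gpr = g1("ATPM_n"))
    } else {
      add("ATPM_a", c(atp_a = -1, adp_a = 1, pi_a = 1), 0.1, 100,
          gpr = g1("ATPM_a"))
    }
  }
  # ANLS arm
  if ("lactate" %in% ex) {
    add("LACex_a", c(lac_a = -1, lac_e = 1), 0, 100, obj = 1,
        gpr = g1("LACex_a"))
    add("LACt_n", c(lac_e = -1, lac_n = 1), 0, 100, obj = 1,
        gpr = g1("LACt_n"))
  }
  # sodium pump arm: 3 Na extruded per ATP
  if ("sodium" %in% ex) {
    add("NAK_n", c(atp_n = -1, na_n = -3, adp_n = 1, pi_n = 1, na_e = 3),
        0, 1000, obj = 1, gpr = "g_nak_n_1 or g_nak_n_2")
    add("NALEAK_n", c(na_e = -1, na_n = 1), 0, 1000, gpr = g1("NALEAK_n"))
  }
  # glutamate-glutamine cycle arm
  if (all(c("glutamate", "glutamine") %in% ex)) {
    add("VGLU_n", c(glu_n = -1, glu_e = 1), 0, 100, obj = 1,
        gpr = g1("VGLU_n"))
    add("GLUt_a", c(glu_e = -1, glu_a = 1), 0, 100, gpr = g1("GLUt_a"))
    add("GLNS_a", c(glu_a = -1, atp_a = -1, gln_a = 1, adp_a = 1,
                    pi_a = 1), 0, 100, gpr = g2("GLNS_a"))
    add("GLNex_a", c(gln_a = -1, gln_e = 1), 0, 100, obj = 1,
        gpr = g1("GLNex_a"))
    # sodium-coupled glutamine uptake (SNAT-like)
    add("GLNt_n", c(gln_e = -1, na_e = -1, gln_n = 1, na_n = 1), 0, 100,
        gpr = g1("GLNt_n"))
    add("GLS_n", c(gln_n = -1, glu_n = 1), 0, 100, gpr = g2("GLS_n"))
  }

  # planted hubs: high-degree salvage lumps touching many core metabolites.
  # The astrocytic hub bridges six intracellular species; the neuronal hub
  # additionally touches extracellular lactate, bridging the two cells.
  hub_ids <- spec$planted_hub_reactions
  for (cell in c("n", "a")) {
    hub <- grep(paste0("_", cell, "$"), hub_ids, value = TRUE)
    if (!length(hub)) next
    s <- function(m) paste0(m, "_", cell)
    if (cell == "a") {
      add(hub[1], stats::setNames(c(-0.01, -0.01, -0.01, -0.01, -0.01, 0.05),
          c(s("glc"), s("pyr"), s("o2"), s("glu"), s("gln"), s("lac"))),
          0, 0.1, gpr = g3(hub[1]))
    } else {
      add(hub[1],
          stats::setNames(c(-0.01, -0.01, -0.01, -0.01, -0.01, -0.01, -0.01,
                            0.05),
          c("lac_e", s("glc"), s("pyr"), s("o2"), s("glu"), s("gln"),
            s("na"), s("lac"))),
          0, 0.1, gpr = g3(hub[1]))
    }
  }

  # Topological filler, seeded. The two cells get deliberately different
  # redundancy structure, mirroring the division of labor the analysis
  # probes. Neuron: isozyme duplicates (one- and two-step) of interior
  # zero-reduced-cost reactions form a redundant mesh around the
  # neuronal sensitivity-set reactions -- removing any node lengthens
  # current-flow paths but never disconnects anything, a mild uniform harm.
  # Astrocyte: each irreversible core reaction emits a trace private
  # byproduct drained through a pendant chain to a sink -- removing the
  # core reaction (or any chain link) prunes a whole pendant subtree, which
  # relieves rather than harms the sensitivity set. Filler reactions are
  # value-neutral (duplicates of zero-reduced-cost reactions, or drains of
  # worthless byproducts), so they never enter the sensitivity set.
  with_spec_seed(spec, 101L, {
    for (cell in c("n", "a")) {
      n_fill <- spec$n_core_reactions_per_cell -
        sum(grepl(paste0("_", cell, "$"), names(rxn)))
      if (n_fill <= 0) next
      if (cell == "n") {
        # central-carbon templates only: every copy sits adjacent to the
        # neuronal sensitivity-set anchors, keeping removals uniformly mild
        templates <- intersect(c("HEX_n", "LDH_n", "OXPHOS_n", "O2t_n",
                                 "GLS_n"), names(rxn))
        templates <- sample(templates)
        i <- 1L
        while (i <= n_fill) {
          tmpl <- rxn[[templates[1L + (i - 1L) %% length(templates)]]]
          two_step <- (n_fill - i >= 1L) && stats::runif(1) < 0.5
          if (two_step) {
            w <- sprintf("w%d_n", i)
            lhs <- tmpl$mets[tmpl$mets < 0]
            rhs <- tmpl$mets[tmpl$mets > 0]
            add(sprintf("FIL%d_n", i),
                c(lhs, stats::setNames(1, w)), 0, 0.5,
                gpr = g1(sprintf("FIL%d_n", i)))
            add(sprintf("FIL%d_n", i + 1L),
                c(stats::setNames(-1, w), rhs), 0, 0.5,
                gpr = g1(sprintf("FIL%d_n", i + 1L)))
            i <- i + 2L
          } else {
            add(sprintf("FIL%d_n", i), tmpl$mets, 0, 0.5,
                gpr = g1(sprintf("FIL%d_n", i)))
            i <- i + 1L
          }
        }
      } else {
        hosts <- intersect(c("HEX_a", "OXPHOS_a", "GLUt_a", "GLNS_a",
                             "GLNex_a", "LACex_a"), names(rxn))
        hosts <- sample(hosts)
        i <- 1L; h <- 1L
        while (i <= n_fill) {
          host <- hosts[1L + (h - 1L) %% length(hosts)]; h <- h + 1L
          bp <- paste0("bp_", tolower(host))
          if (!bp %in% names(rxn[[host]]$mets)) {
            rxn[[host]]$mets <- c(rxn[[host]]$mets, stats::setNames(0.001, bp))
          }
          len <- min(sample(2:4, 1), n_fill - i + 1L)
          from <- bp
          for (jj in seq_len(len)) {
            fid <- sprintf("FIL%d_a", i)
            if (jj == len) {
              add(fid, stats::setNames(-1, from), 0, 10, gpr = g1(fid))
            } else {
              tip <- sprintf("f%d_a", i)
              add(fid, stats::setNames(c(-1, 1), c(from, tip)), 0, 10,
                  gpr = g1(fid))
              from <- tip
            }
            i <- i + 1L
          }
        }
      }
    }
  })

  rxn_ids <- names(rxn)
  met_ids <- unique(unlist(lapply(rxn, function(r) names(r$mets))))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn)) S[names(rxn[[j]]$mets), j] <- rxn[[j]]$mets
  metabolic_model(
    metabolite_ids = met_ids, reaction_ids = rxn_ids, S = S,
    lower_bounds = vapply(rxn, `[[`, numeric(1), "lb"),
    upper_bounds = vapply(rxn, `[[`, numeric(1), "ub"),
    objective_coefficients = vapply(rxn, `[[`, numeric(1), "obj"),
    gpr = vapply(rxn, `[[`, character(1), "gpr"))
}

#' Default planted differentially expressed genes
#'
#' One up-regulated sodium-pump/transporter gene and one up-regulated hub
#' gene, plus one down-regulated hub gene, per cell x condition stratum.
#' All planted genes belong to reactions that the pipeline flags as optimal
#' (pump, glucose transporters) or central (hubs), so they are hub genes by
#' construction.
#'
#' @param spec a [synthetic_spec()].
#' @return named list `"<cell>.<condition>" -> list(up =, down =)`.
#' @export
default_planted_de <- function(spec = synthetic_spec()) {
  if (!is.null(spec$planted_de_genes)) return(spec$planted_de_genes)
  list(
    neuron.neurotransmission = list(up = c("g_nak_n_1", "g_hub_n_1"),
                                    down = "g_hub_n_2"),
    neuron.aging = list(up = "g_hub_n_3", down = c("g_nak_n_2", "g_hub_n_1")),
    astrocyte.neurotransmission = list(up = c("g_glct_a_1", "g_hub_a_1"),
                                       down = "g_hub_a_2"),
    astrocyte.aging = list(up = "g_hub_a_3", down = c("g_glct_a_1",
                                                      "g_hub_a_2"))
  )
}

#' Generate differential-expression tables with planted effects
#'
#' Every model gene appears once per cell x condition stratum. Planted
#' up/down genes draw their effect beyond the decision thresholds
#' (neurotransmission fold change in `[1.4, 3.0]` / `[0.3, 0.7]`; aging
#' coefficient in `[0.01, 0.05]` with sign by direction) and their
#' significance below the cutoff. All other genes draw a null effect inside
#' the dead zone (fold change in `[0.85, 1.15]`, coefficient in
#' `[-0.003, 0.003]`) so no null gene can pass the filters regardless of its
#' significance, which is uniform on `[0, 1]`.
#'
#' @param model the [generate_toy_network()] output.
#' @param spec the same [synthetic_spec()].
#' @return DE data.frame (see [read_de_table()]).
#' @export
generate_de_tables <- function(model, spec = synthetic_spec()) {
  genes <- model_genes(model)
  planted <- default_planted_de(spec)
  missing <- setdiff(unlist(planted), genes)
  if (length(missing)) {
    stop("planted gene(s) absent from model: ", paste(missing, collapse = ", "))
  }
  with_spec_seed(spec, 202L, {
    out <- list()
    for (cell in c("neuron", "astrocyte")) {
      for (cond in c("neurotransmission", "aging")) {
        key <- paste(cell, cond, sep = ".")
        up <- planted[[key]]$up; down <- planted[[key]]$down
        eff <- sig <- stats::setNames(numeric(length(genes)), genes)
        if (cond == "neurotransmission") {
          eff[] <- stats::runif(length(genes), 0.85, 1.15)
          eff[up] <- stats::runif(length(up), 1.4, 3.0)
          eff[down] <- stats::runif(length(down), 0.3, 0.7)
          sig[] <- stats::runif(length(genes))
          sig[c(up, down)] <- stats::runif(length(c(up, down)), 0.001, 0.049)
        } else {
          eff[] <- stats::runif(length(genes), -0.003, 0.003)
          eff[up] <- stats::runif(length(up), 0.01, 0.05)
          eff[down] <- -stats::runif(length(down), 0.01, 0.05)
          sig[] <- stats::runif(length(genes))
          sig[c(up, down)] <- stats::runif(length(c(up, down)), 5e-4, 9e-3)
        }
        out[[key]] <- data.frame(gene_id = genes, effect = unname(eff),
                                 significance = unname(sig), cell = cell,
                                 condition = cond, stringsAsFactors = FALSE)
      }
    }
    de <- do.call(rbind, out)
    rownames(de) <- NULL
    validate_de_table(de)
  })
}

#' Generate a gene-set collection with one planted pathway
#'
#' Emits at least three sets over the model's genes: a planted pathway
#' holding four planted differentially expressed hub genes plus one bystander
#' (constructed to be over-represented among recovered differential hub
#' genes), a central-carbon set, and two random filler sets.
#'
#' @param model the [generate_toy_network()] output.
#' @param spec the same [synthetic_spec()].
#' @return named list of gene sets (GMT-writable with [write_gmt()]).
#' @export
generate_pathway_sets <- function(model, spec = synthetic_spec()) {
  genes <- model_genes(model)
  if (!length(genes)) stop("model has no genes")
  planted <- unique(unlist(default_planted_de(spec)))
  planted <- intersect(planted, genes)
  with_spec_seed(spec, 303L, {
    bystander <- sample(setdiff(genes, planted), 1)
    sets <- list(
      planted_pathway = c(planted[seq_len(min(4, length(planted)))],
                          bystander),
      central_carbon = intersect(genes, c(
        "g_hex_n_1", "g_hex_n_2", "g_hex_a_1", "g_hex_a_2",
        "g_glct_n_1", "g_glct_a_1", "g_ldh_n_1", "g_ldh_a_1")),
      filler_set_1 = sample(genes, min(8, length(genes))),
      filler_set_2 = sample(genes, min(6, length(genes)))
    )
    attr(sets, "description") <- c("planted over-represented pathway",
                                   "glycolysis and transport",
                                   "random filler", "random filler")
    sets
  })
}

#' Generate an ortholog-style identifier mapping table
#'
#' Identity mapping over the model's genes with a couple of deliberately
#' unmapped filler genes, to exercise the unmapped-report path without
#' touching the planted ground truth.
#'
#' @param model the [generate_toy_network()] output.
#' @param spec the same [synthetic_spec()].
#' @return data.frame with columns `source`, `target`.
#' @export
generate_mapping <- function(model, spec = synthetic_spec()) {
  genes <- model_genes(model)
  drop <- grep("^g_fil1_", genes, value = TRUE)
  keep <- setdiff(genes, drop)
  data.frame(source = keep, target = keep, stringsAsFactors = FALSE)
}

#' Write the full synthetic bundle to a directory
#'
#' Materializes the model (JSON dialect), the DE table (TSV), the gene-set
#' collection (GMT) and the mapping table (TSV) for a given spec.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synthetic_spec()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(dir, spec = synthetic_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- generate_toy_network(spec)
  paths <- c(model = file.path(dir, "model.json"),
             de = file.path(dir, "de_table.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             mapping = file.path(dir, "orthologs.tsv"))
  write_model(model, paths["model"], "json")
  write_de_table(generate_de_tables(model, spec), paths["de"])
  write_gmt(generate_pathway_sets(model, spec), paths["gmt"])
  utils::write.table(generate_mapping(model, spec), paths["mapping"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
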