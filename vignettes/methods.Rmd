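---
title: "Methods: optimality, induced centrality and differential hub genes in a two-cell metabolic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimality, induced centrality and differential hub genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the method left room.

## The coupled-objective flux balance analysis

A two-cell (neuron + astrocyte) constraint-based model is a stoichiometric
matrix $S$ (metabolites × reactions), flux bounds $L_b \le v \le U_b$ in
μM/s, and a linear objective $c$. FBA solves

$$\max_v \; z = c^\top v \quad \text{s.t.} \quad S v = 0,\; L_b \le v \le U_b.$$

The neurotransmission objective places weight 1 on exactly five coupled flux
carriers: the neuronal Na⁺/K⁺-ATPase (one flux unit hydrolyzes one ATP and
extrudes three Na⁺), astrocytic lactate export and neuronal lactate import
(the lactate-shuttle arm), and neuronal vesicular glutamate export plus
astrocytic glutamine export (the glutamate–glutamine cycle arm). Maximizing
their sum models a tissue committed to sustaining transmission.

Measured constants parameterize the bounds (`fba_constants()`):

| constant | value | unit | role |
|---|---|---|---|
| sodium efflux after stimulation | 350 | μM/s | pump workload |
| Na⁺ per ATP | 3 | – | pump stoichiometry |
| housekeeping ATP demand | 38 | μM/s | fixed neuronal maintenance flux |
| resting neuronal glucose uptake | 0.9 | μM/s | glycolysis baseline |
| stimulation fold change | 2.353 | – | stimulated glycolysis 2.1177 μM/s |
| ATP yield per glucose | 31 | – | 2 glycolytic + 14.5 per pyruvate |
| astrocytic O₂ uptake | 0.01666 | μM/s | keeps the astrocyte glycolytic |

Derived: pump ATP = 350/3 ≈ 116.7 μM/s; total neuronal demand = 38 + 350/3 ≈
154.7 μM/s; neuronal glycolytic ATP ≈ 65.6 μM/s — the shortfall is exactly
what the lactate shuttle must supply. `fit_astrocytic_glycolysis()` finds, by
bisection to 10⁻⁴ on the bound, the smallest astrocytic glucose-uptake bound
whose FBA optimum delivers the demand; the achieved neuronal ATP production
is measured from the positive part of the ATP row of $S\,\mathrm{diag}(v)$.

**LP implementation.** The solver is a dense bounded-variable two-phase
revised simplex written for this package (`lp_bounded`): Dantzig pricing
with an automatic switch to Bland's rule after a degenerate stall, signed
phase-1 artificials, and exact basis duals $y$ solving $B^\top y = c_B$, so
reduced costs $\delta = c - S^\top y$ come out of the optimal basis rather
than from a post-hoc fit. Mass-balance LPs are maximally degenerate (the
right-hand side is all zeros), which is why the anti-cycling fallback and
exact bound-snapping matter. The test suite checks the optimum against
brute-force vertex enumeration on small random models (10⁻⁶) and the reduced
costs against finite-difference bound perturbations (10⁻⁴). On degenerate
optima the returned $v$, $\delta$ are those of the deterministic final
basis, making outputs reproducible; no uniqueness is assumed.

Sign convention: $\delta_i > 0$ at an active bound means relaxing that bound
upward increases $z$. Uptakes are negative exchange fluxes; transporter
fluxes are positive. The *sensitivity set* $s$ collects reactions with
$|\delta_i| > 10^{-9}$.

**Phenotypic phase planes.** `compute_phpp()` fixes both bounds of the
designated oxygen and glucose uptake reactions to each grid value (the
paired inequalities collapse to an equality — reading the method's loop
literally) and stores the full optimal flux vector per cell, with
infeasible cells flagged. A non-zero slope of the optimal surface means the
optimum depends on the scanned substrate.

## Absolute Optimality

Fluxes and reduced costs live on very different, signed scales, so both are
passed through the signed pseudo-logarithm and min–max rescaled:

$$N(z_i) = \mathrm{scale}_{[0,1]}\!\big(\operatorname{asinh}(z_i/2)\big),
\qquad AO_i = \big\| (N(v_i), N(\delta_i)) \big\|_2 \in [0, \sqrt2].$$

The printed form of the transform is ambiguous about a squared term and a
logarithm-base constant; we use the unsquared signed form with constant
$1/\ln 10$. The choice is almost immaterial: any positive multiplicative
constant is annihilated by the rescale (a tested invariance), and squaring
would only destroy the sign information that "signed pseudo logarithm"
promises to keep. Normalization runs over the whole network per quantity
(the transform is stated once per quantity); per-cell normalization and
absolute-value-before-normalization are available as arguments
(`per_cell`, `abs_before_norm`) but off by default.

Reactions with AO at or above the per-cell 90th percentile (type-7 linear
interpolation between order statistics; ties kept via ≥) are the *optimal*
reactions. Percentiles are computed per cell — matching the treatment of the
centrality cutoff, which the method states per cell — with exchange
reactions pooled into both cellular strata, since the extracellular space
borders both cells. Cell distributions are compared with a two-sided
Wilcoxon rank-sum test.

## Induced centrality and the Absolute Centrality Contribution

Topology is probed on the *reaction projection* of $S$: nodes are reactions,
and two reactions are joined if they share a metabolite with non-zero
coefficient in both columns; the edge weight counts shared metabolites but
centralities treat the graph as unweighted and undirected (no directionality
is stated for the projection, and weighting is left as a flag). ATP, ADP
and inorganic phosphate are excluded by default (`currency_metabolites()`):
cofactor pools touch nearly every energy-coupled reaction and would weld the
projection into one clique that hides the substrate backbone.

For a centrality $C$ (eigenvector, closeness, or information), the basal
cohesiveness of the sensitivity set is $C_{basal} = \frac1k \sum_{i \in s}
C_i$. Removing node $x$ and recomputing over the surviving members gives
$C_{-x}$, and the induced centrality is the log fold change

$$I_C(x) = \log_2 \frac{C_{basal}}{C_{-x}},$$

with means over $s \setminus \{x\}$ when $x \in s$, means floored at
10⁻¹² before the ratio (warned), and $I_C(x) = 0$ when nothing of $s$
survives. Removal candidates are reactions only — the method operates on the
reaction projection, not the bipartite graph.

Metric conventions, chosen to be exact on closed-form cases frozen in the
tests:

* **eigenvector** — principal eigenvector of the adjacency per connected
  component, by deterministic power iteration (uniform start, tolerance
  10⁻¹⁰, small diagonal shift so bipartite components converge),
  max-normalized within the component; singletons score 0.
* **closeness** — Wasserman–Faust scaled form
  $\frac{r-1}{N-1}\cdot\frac{r-1}{\sum d}$ over the $r$ reachable vertices,
  well-defined on disconnected graphs (removals can disconnect).
* **information** — the classic Stephenson–Zelen current-flow form
  $I_i = [C_{ii} + (T - 2R_i)/n]^{-1}$ with $C = (L + J)^{-1}$ per
  component. The reciprocal-total-effective-resistance variant common in
  Python network libraries equals this divided by the component size; the
  two differ under node removal (the size changes), and we keep the form
  the method names.

Aggregation mirrors the optimality index: the eigenvector term is the
probability of interaction, the distance/current terms its cost,

$$P_s(x) = N(I_{eig}(x)), \quad C_s(x) = N(I_{clo}(x)) + N(I_{inf}(x)),
\quad ACC_s(x) = \|(P_s, C_s)\|_2 \in [0, \sqrt5],$$

and the per-cell top decile of ACC are the *central* reactions.

**Clustering QC.** Each reaction is a variable whose samples are its induced
centralities; the reaction × reaction Pearson matrix is clustered
(complete linkage, Euclidean distance between correlation rows) and
projected by PCA. The separation score is the fraction of cellular reactions
whose 2-cluster assignment matches their cell label (maximized over the two
label permutations; exchange reactions excluded from the score). The QC
defaults to the three normative metrics; betweenness can be added as a
fourth sample (`qc_betweenness = TRUE`) — the original description mentions
four metrics without naming the fourth, and the aggregation equations define
exactly three, so the fourth is a hook rather than part of ACC. On the
synthetic models, including betweenness makes the dominant correlation axis
the cross-cell shuttle arm rather than cell identity, one reason it is not
the default.

## Hub genes, differential expression, enrichment

Gene–reaction (GPR) boolean strings are flattened to gene sets
(`parse_gpr`); the union over optimal ∪ central reactions gives the *hub
genes*, with per-gene provenance. An optional two-column table maps
identifiers (the local stand-in for an ortholog service); one-to-many
mappings expand, unmapped sources are reported.

Differential-expression thresholds are applied literally, inclusive on the
effect and strict on the significance: neurotransmission fold change ≥ 1.3
(up) or ≤ 0.77 (down) with adjusted p < 0.05; aging coefficient ≥ 0.005 or
≤ −0.005 (the magnitude corresponds to roughly a 10% fold change, with the
sign deciding direction) with FDR < 0.01. DHG per cell × condition stratum
are hub ∩ (up ∪ down), direction-tagged. Over-representation uses the
hypergeometric upper tail per gene set (only sets overlapping the query in
at least 2 genes are tested) with Benjamini–Hochberg adjustment across
tested sets — a generic replacement for interactive enrichment tools, which
additionally fuse related terms and curate them manually; that layer is out
of scope here.

## The synthetic two-cell generator

`generate_toy_network()` builds, per cell, a lumped glycolysis →
pyruvate → oxidative-phosphorylation skeleton (31 ATP per fully oxidized
glucose), joined by the lactate-shuttle and glutamate–glutamine arms and the
neuronal sodium pump (3 Na:1 ATP, fed by a leak; glutamine uptake is
Na-coupled, which keeps the sodium arm attached to the substrate graph).
The measured constants above are installed as the default bounds, so the
fitted model reproduces their arithmetic: the pump carries 350/3 μM/s of
ATP, and sodium efflux is 350 μM/s by stoichiometric identity. Default size
is 30 reactions per cell plus 4 exchanges — small enough that the LP and the
full node-removal loop run in about a second, large enough for meaningful
deciles.

Ground truth is planted at three levels:

* **Hub reactions** (one per cell) are high-degree salvage connectors
  touching many core metabolites; the neuronal hub also bridges
  extracellular lactate. Their removal reshapes paths around the
  sensitivity set more than any other single removal, which is what the
  top-decile-ACC recovery checks.
* **Topological filler** gives the cells opposite redundancy structure,
  emulating the division of labor the method detected in the real network:
  the neuron carries an isozyme mesh (one- and two-step duplicates of
  interior, zero-reduced-cost reactions) around its sensitivity-set
  members, so removing any neuron node mildly harms the set; the astrocyte
  carries pendant byproduct-drain chains (each irreversible core reaction
  emits a trace private byproduct drained to a sink), so removing any
  astrocyte node prunes a pendant subtree and relieves the set. Oppositely
  signed induced-centrality profiles are exactly what the clustering QC is
  designed to detect; the two hubs, as harming bridges, are the deliberate
  exceptions. Filler is value-neutral by construction (duplicates of
  zero-reduced-cost reactions, or drains of worthless byproducts), so the
  sensitivity set is independent of the filler layout.
* **DE genes** are planted per stratum on reactions that are optimal (the
  pump, the astrocytic glucose transporter) or central (the hubs) by
  construction: effects land beyond the thresholds (FC in [1.4, 3.0] /
  [0.3, 0.7]; coefficients in ±[0.01, 0.05]) with significance below the
  cutoffs, while every other gene draws a null effect inside the dead zone
  (FC in [0.85, 1.15]; coefficient in ±0.003) with uniform significance —
  so no null can pass regardless of its p-value, and filter tests are exact
  rather than probabilistic. A planted pathway of hub DHGs makes the
  enrichment stage testable.

Everything is a pure function of the seed (verified byte-for-byte on the
written bundle). What the generator does *not* emulate: the real
reconstruction's reaction inventory and compartmentalization, transcript
count noise (effects and p-values are drawn directly), correlated
expression, many-to-many orthology, or thermodynamic constraints. Passing
the recovery tests therefore shows the pipeline is correct and sensitive
under its own assumptions — not that the biological findings of any
particular dataset follow.

## Problem sizes and runtime choices

Tests and the acceptance script use models of 64 reactions (30 per cell),
20 simulation seeds for the stochastic recovery rates, vertex-enumeration
cross-checks on ≤ 8-reaction random models, removal-oracle cross-checks on
≤ 50-node graphs, and exhaustive hypergeometric enumeration up to a
background of 20 — sizes at which every oracle is exact and the whole suite
runs in a few minutes on one CPU.

## Known limitations

* Reduced costs at degenerate optima are basis-dependent; any returned
  vector is a valid subgradient, but finite-difference agreement is only
  guaranteed where the optimum is non-degenerate (the cross-checks use
  generic random data for this reason).
* The external genome-scale neuron–astrocyte reconstruction is not
  redistributable here; `reproduce_published_fba()` implements the
  published constraint protocol and is exercised only when a local copy is
  supplied, and the corresponding check fails visibly otherwise.
* Enrichment is plain over-representation; term fusion, kappa grouping and
  manual curation of the interactive tools it replaces are out of scope.
* The SBML dialect covers Level 3 core with flux-bound parameters and
  annotation-carried GPR/labels/objective — enough for lossless round trips
  of this package's models, not a general-purpose SBML implementation.
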