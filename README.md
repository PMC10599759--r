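# neurometnet

Integrative analysis of the neuron–astrocyte metabolic network: flux balance
analysis with a coupled neurotransmission objective, reduced-cost sensitivity,
Absolute Optimality and node-removal induced centrality, and integration of
the resulting hub genes with differential-expression tables into
**differential hub genes (DHG)**.

## The problem

During glutamatergic neurotransmission the neuron faces an acute energy
workload: re-establishing ion gradients after stimulation consumes ATP at the
Na⁺/K⁺-ATPase (3 Na⁺ extruded per ATP), on top of a housekeeping demand. The
astrocyte supports this through the astrocyte–neuron lactate shuttle (ANLS)
and the glutamate–glutamine cycle (GGC). This package asks, for a two-cell
constraint-based model of that system: *which reactions make the optimal
response possible, which reactions topologically sustain them, and which of
their genes are differentially regulated during neurotransmission or brain
aging?*

The pipeline, for a model with stoichiometry S, bounds L_b ≤ v ≤ U_b and
objective c:

1. **FBA** — maximize z = cᵀv subject to Sv = 0 and the bounds, with c = 1 on
   the five coupled neurotransmission fluxes (sodium pump, the two
   lactate-shuttle transporters, vesicular glutamate export, glutamine
   export). The astrocytic glycolytic bound is fitted by bisection so the
   optimum meets the measured neuronal ATP demand.
2. **Sensitivity** — reduced costs δᵢ = ∂z/∂vᵢ from the LP dual; reactions
   with δᵢ ≠ 0 form the *sensitivity set* s.
3. **Absolute Optimality** — AOᵢ = ‖(N(vᵢ), N(δᵢ))‖₂ where N is the signed
   pseudo-logarithm asinh(z/2)/ln 10 min–max rescaled to [0, 1]; the per-cell
   top decile are the *optimal* reactions.
4. **Absolute Centrality Contribution** — on the reaction projection of S
   (nodes: reactions; edges: shared non-currency metabolites), each node x is
   removed and the mean eigenvector / closeness / information centrality of s
   is recomputed: I_c(x) = log₂(C_basal / C₋ₓ). Then P_s = N(I_eig),
   C_s = N(I_clo) + N(I_inf) and ACC = ‖(P_s, C_s)‖₂; per-cell top decile are
   the *central* reactions. A Pearson-correlation / complete-linkage / PCA QC
   checks that the induced-centrality profiles separate the two cells.
5. **Integration** — genes of optimal ∪ central reactions (via gene–reaction
   rules) are the *hub genes*; intersected per cell × condition with
   differential-expression tables (neurotransmission: FC ≥ 1.3 or ≤ 0.77,
   adjusted p < 0.05; aging: |coefficient| ≥ 0.005, FDR < 0.01) they yield the
   DHG, which are tested for pathway over-representation (hypergeometric +
   Benjamini–Hochberg).

A seeded synthetic-data generator builds feasible two-cell models with the
measured flux constants installed, planted hub reactions and planted
differentially expressed genes, so every stage is testable against known
ground truth without external downloads.

## Worked example

```r
library(neurometnet)

spec  <- synthetic_spec(seed = 1)
model <- generate_toy_network(spec)
res   <- run_hub_pipeline(model,
                          generate_de_tables(model, spec),
                          generate_pathway_sets(model, spec),
                          mapping = generate_mapping(model, spec))

res$solution
#> FBASolution: status=optimal, z=141.23, 7/64 reactions with |reduced cost|>1e-9
res$solution$v[c("LACex_a", "NAK_n")]
#>  LACex_a    NAK_n
#> 6.139195 116.667  # lactate shuttled to the neuron; pump ATP = 350/3
res$sensitivity$s
#> "EX_lac" "GLCt_n" "ATPM_n" "GLCt_a" "O2t_a" "ATPM_a" "HUB_n"
res$qc$separation
#> 0.9      # induced-centrality clustering separates neuron from astrocyte
res$dhg
#> DHGResult: 20 hub genes
#>   neuron.neurotransmission     3 DHG (2 up, 1 down)
#>   neuron.aging                 3 DHG (1 up, 2 down)
#>   astrocyte.neurotransmission  3 DHG (2 up, 1 down)
#>   astrocyte.aging              3 DHG (1 up, 2 down)
res$enrichment[1, c("set_name", "p_value", "fdr")]
#>          set_name      p_value          fdr
#> 1 planted_pathway 0.0005452609 0.0005452609
```

The fitted astrocytic glucose-uptake bound is 3.073 μM/s, the astrocytic
lactate efflux 6.14 μM/s, and the neuronal sodium efflux 350 μM/s — the
pump flux exactly absorbs the ATP left after the 38 μM/s housekeeping drain.
The recovered DHG are exactly the planted ones in every stratum.

The same analysis, written out step by step with intermediate tables under
`results/`, lives in `analysis/01_simulate.R` … `analysis/05_integration.R`.

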