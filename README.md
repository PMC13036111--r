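# isingbridge

Symptom-network analysis for binarized questionnaire data: Ising network
estimation, bridge centrality between two symptom communities, and simulated
threshold interventions that rank which symptom is the most promising
treatment target.

The package is aimed at network-psychometrics workflows in which two
instruments (say, a mind-wandering scale and a problematic-media-use scale)
are administered to the same sample, responses are dichotomized into symptom
present/absent, and the question is which symptoms *bridge* the two symptom
clusters — and what a simulated intervention on each symptom would do to
overall severity.

## The model

Item states are coded x ∈ {0,1}ᵖ ("inactive"/"active"). The joint
distribution is the Ising model

P(x) ∝ exp( Σᵢ τᵢ xᵢ + Σ_{i<j} ω_{ij} xᵢ xⱼ )

where τᵢ (threshold) is symptom i's autonomous activation tendency on the
log-odds scale and ω_{ij} (edge weight) the conditional association between
symptoms i and j given all others. The pipeline:

1. **Binarize** 1–5 Likert responses: 1 → 0 (not present), 2–5 → 1 (present).
2. **Estimate** (τ, ω) by eLasso: one L1-penalized logistic regression per
   node on all other nodes (glmnet), penalty chosen per node by the EBIC
   with sparsity parameter γ (default 0.25), coefficient pairs symmetrized
   by averaging under an AND (default) or OR rule.
3. **Bridge centrality** against the fixed instrument partition: bridge
   strength, bridge expected influence, bridge betweenness, bridge
   closeness, plus one-step expected influence; case-dropping bootstrap
   stability summarized by the CS coefficient.
4. **Intervention simulation**: for each candidate symptom, shift its
   threshold by ±2 SD of the threshold vector (alleviating/aggravating),
   draw 5,000 observations from the perturbed network (exact sampling up to
   20 items, Gibbs beyond), and compare sum scores against baseline with
   Welch t-tests, Benjamini–Hochberg FDR correction, and ranking by
   absolute mean difference.

A synthetic-data module generates ground-truth networks with a known bridge
structure (two communities of 5 and 13 items, three planted bridges with one
dominant), so every stage is verifiable end to end without access to any
particular study's raw data.

## Worked example

```r
library(isingbridge)

truth  <- make_ground_truth(ground_truth_spec())        # planted 18-item network
likert <- expand_to_likert(generate_dataset(truth, n = 1989, seed = 2024), seed = 9)
binary <- binarize_likert(likert)

head(item_descriptives(likert, binary), 4)
#>   item  community  mean    sd endorsement
#> 1 MW1   MW         2.31  1.50       0.521
#> 2 MW2   MW         2.39  1.50       0.550
#> 3 MW3   MW         2.23  1.48       0.497
#> 4 MW4   MW         1.58  1.17       0.238

est <- estimate_network(binary, gamma = 0.25, rule = "AND")
est
#> <ising_network> 18 items, 24 edges
#> communities: MW (5), PSVU (13)

dplyr::filter(tidy(est), bridge)      # recovered cross-community edges
#>   item_a item_b weight bridge
#> 1 MW5    PSVU8   0.467 TRUE
#> 2 MW5    PSVU3   0.334 TRUE
#> 3 MW1    PSVU5   0.150 TRUE

bridge_indices(est)                   # MW5 is the strongest bridge (z = 3.18)

res <- run_nira(est, candidate_items = paste0("MW", 1:5),
                n_sim = 5000, master_seed = 11)
glance(res)
#>   direction   top_target top_mean_difference top_p_adjusted n_significant
#> 1 aggravating MW1                      0.422       9.84e-19             5
#> 2 alleviating MW5                     -0.317       5.83e-11             5
```

Reading the output: each symptom's endorsement is the fraction of the
sample with the symptom present after binarization; the three `bridge`
edges are the (shrunken) estimates of the planted cross-community weights
0.8, 0.4, 0.35; and the intervention table says that an alleviating
intervention on the dominant bridge symptom MW5 is projected to lower the
mean network sum score by 0.32 active symptoms (Welch t ≈ −7, FDR-adjusted
p ≈ 6e−11) — the largest alleviating effect, so MW5 ranks first as the
intervention target. `autoplot()` methods draw the weight-matrix heatmap,
the standardized centrality profile, and the intervention dot-and-CI panel.

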