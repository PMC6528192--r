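# gdagnet

Genome-anchored causal networks for metabolomic data.

## The problem

Exome studies find loss-of-function (LoF) variants associated with several
serum metabolites at once. That pattern has two very different
explanations: the gene really has multiple functions (pleiotropy), or it
perturbs one metabolite and the metabolome's own dependency structure
carries the signal onward (mediation). Telling these apart requires knowing
the directed relationships *among* the metabolites — which ordinary
association scans never estimate.

`gdagnet` implements the full analysis chain for researchers working with
cohort-scale exome + metabolomics data:

* **Selection** — gene-burden / single-variant linear scans under
  Bonferroni control (`single_variant_scan()`, `bonferroni_threshold()`),
  joint L1-penalized selection over all gene burdens with min-BIC tuning
  over the grid {1.5, 0.3, 0.01} (`ccrs_select()`), and the intersection of
  the two routes (`intersect_selections()`).
* **Instruments** — hierarchical clustering of LD proxies (|r| > 0.80,
  `cluster_proxies()`) followed by PCA of the representatives, retaining
  the components that explain more than 90% of variance
  (`build_instruments()`). Because inherited variation precedes metabolite
  levels, these orthogonal scores act as instrumental variables in the
  sense of Mendelian randomization.
* **Network** — constraint-based learning over instruments + metabolites
  (`learn_gdag()`): PC-stable skeleton search with Gaussian partial
  correlations (Fisher z), every instrument–metabolite edge anchored
  instrument → metabolite, collider detection by supermajority vote over
  separating sets, Meek propagation, and conditional-independence level
  tuning by subsample stability under the structural Hamming distance
  (`tune_alpha()`, grid {0.0005, 0.001, 0.005, 0.01, 0.05}, 45 replicates).
* **Structural equations** — per metabolite $M_i$:
  $M_i = \sum_j \lambda_{ij} M_j + U_i$ and
  $U_i = \sum_m \gamma_{im} G_m + e_i$, estimated equation-by-equation by
  OLS (`fit_sem()`); `assess_pleiotropy()` classifies each selected
  gene–metabolite pair as `direct`, `mediated`, or `not_significant`, and
  calls a gene pleiotropic only with ≥ 2 direct effects.
* **Modules** — deterministic greedy-modularity community detection on the
  metabolite subgraph with neighbour lists and pathway overlays
  (`detect_modules()`, `lof_module_overlay()`).
* **Synthetic data** — a generator with known causal ground truth
  (`simulate_study()`, `make_scenario()`, `simulate_genotypes()`,
  `inject_missingness()`), used to validate every stage.

## Worked example

A gene drives decanoylcarnitine (effect 1.5 SD per allele, MAF 8%), and
decanoylcarnitine drives octanoylcarnitine (λ = 0.5) — so the gene is
*associated* with both metabolites, but directly influences only one:

```r
library(gdagnet)
cfg <- run_config(scenario = "bnipl_like", n_samples = 2000, seed = 7)
res <- run_pipeline(cfg)

res$selection$selection$pairs[, c("unit", "metabolite", "beta", "p_value")]
#>      unit        metabolite      beta       p_value
#> 1 GENE001 decanoylcarnitine 0.7364222  0.000000e+00
#> 2 GENE001 octanoylcarnitine 0.4863338 4.208773e-206

network_edges(res$network)
#>              source            target     type source_type target_type
#> 3 decanoylcarnitine octanoylcarnitine directed  metabolite  metabolite
#> 1              PC01 decanoylcarnitine directed  instrument  metabolite
#> 2              PC02 decanoylcarnitine directed  instrument  metabolite

res$pleiotropy[["GENE001"]]
#> <pleiotropy_call> GENE001: not pleiotropic
#>         metabolite conditional_beta conditional_p  verdict
#>  decanoylcarnitine     0.7364221767      0.000000   direct
#>  octanoylcarnitine     0.0006356229      0.959453 mediated
```

Both routes select both metabolites (betas in metabolite-SD units). The
learned network puts the genetic instruments upstream of decanoylcarnitine
and orients decanoylcarnitine → octanoylcarnitine. Conditioning on that
edge collapses the gene's effect on octanoylcarnitine from 0.49 SD to
0.0006 SD (p = 0.96): the second association is mediated, and the
pleiotropy hypothesis is rejected — with only one direct effect the gene is
not pleiotropic.

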