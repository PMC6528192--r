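---
title: "From loss-of-function variants to metabolomic causal networks: the methods behind gdagnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From loss-of-function variants to metabolomic causal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdagnet)
```

## The problem

Association scans connect genetic variants to traits but say little about
*how* the connection works. When the traits are serum metabolites, much of
an apparent multi-trait signal can be secondhand: a gene perturbs one
metabolite, and the metabolome's own dependency structure carries the
perturbation to others. A gene that looks associated with five metabolites
may directly influence only one.

`gdagnet` implements a systems pipeline that separates these cases:

1. **Selection.** Find loss-of-function (LoF) gene–metabolite associations
   with two independent routes — a per-unit linear scan under Bonferroni
   control and a joint L1-penalized regression over all gene burdens with
   BIC tuning — and keep only the pairs both routes agree on.
2. **Instruments.** Compress the genotype matrix into mutually orthogonal
   principal-component scores after collapsing near-perfect LD proxies
   (|r| > 0.80). Because inherited variation is assigned before any
   metabolite value exists, these scores are exogenous: valid instrumental
   variables in the sense of Mendelian randomization.
3. **Network.** Learn a causal network over instruments + metabolites with
   a constraint-based search (PC-stable skeleton, collider detection, Meek
   propagation), with every instrument–metabolite edge anchored as
   instrument → metabolite. The conditional-independence level is either
   fixed at 0.001 or tuned by subsample stability using the structural
   Hamming distance (SHD).
4. **Structural equations.** For each metabolite $M_i$ with network
   parents $\{M_j\}$ and tested gene burdens $\{G_m\}$:
   $$M_i = \sum_j \lambda_{ij} M_j + U_i, \qquad
     U_i = \sum_m \gamma_{im} G_m + e_i .$$
   $\lambda_{ij} \ne 0$ corresponds to the metabolite edge $j \to i$ and
   $\gamma_{im} \ne 0$ to a *direct* gene effect $m \to i$. A gene whose
   $\gamma$ survives conditioning for at least two metabolites is called
   pleiotropic; a metabolite whose $\gamma$ vanishes but that is reachable
   from a direct target through directed edges is classified *mediated*.
5. **Modules.** Community detection on the metabolite subgraph summarizes
   densely connected groups and overlays the selection results by pathway.

Everything is validated against a synthetic-data generator with known
causal ground truth, because the real cohort data such pipelines target are
controlled-access.

## The synthetic-data generator

The generator emulates the structure of a cohort-scale exome + serum
metabolomics study.

**Genotypes.** Variants come in LD blocks. Each block has a source variant;
a proxy variant copies each source haplotype allele with probability $r$
(the target within-block correlation) and redraws it from the block allele
frequency otherwise. This makes the *expected dosage correlation equal to
$r$ exactly* while preserving the marginal MAF — a latent-Gaussian
threshold model was rejected because thresholding attenuates the realized
Pearson correlation below its latent target at moderate allele
frequencies. Optional latent ancestry factors shift block allele
frequencies on the logit scale and load on metabolite means, so covariate
adjustment has genuine confounding to remove.

**Metabolite DAG.** A random topological order plus independent forward
edges with probability $2d/(p-1)$ gives an acyclic graph with an expected
$d$ parents per node. Edge coefficients are uniform on an effect range with
random sign.

**Metabolites.** Generated in topological order from the structural
equations above, plus covariate terms (age, sex, BMI, measurement phase,
ancestry factors) and Gaussian noise. Two variance conventions are
offered:

* `standardize = "none"` evaluates the equations literally; coefficients
  are recovered by OLS on the raw columns. The named scenarios use this,
  so a scenario built with $\lambda = 0.5$, $\gamma = 1.5$ is recovered at
  exactly those values.
* `standardize = "children"` rescales each metabolite to unit SD as it is
  generated, so parents enter each child equation on the SD scale and the
  *recorded truth is rescaled to remain the exact structural coefficients
  of the returned data*. The study generator uses this convention: under
  the raw recursion, variance compounds along the topological order and
  overlapping pathways frequently near-cancel, which caps skeleton
  recovery for *any* conditional-independence-based learner well below
  what the same effects support on the standardized scale. Effects quoted
  as "0.3–0.8 SD" mean this convention.

**Study conditions** (defaults of `simulate_study()`, chosen once as a
realistic mQTL regime): 20 metabolites, 2 expected parents per node,
metabolite effects 0.3–0.8 SD, 10 of 20 metabolites instrumented by one
gene each (LD block of 3 variants, within-block $r = 0.9$, MAF 0.15–0.30),
gene effect 0.5 SD per burden allele — genetic $R^2 \approx$ 0.2–0.3 for an
instrumented metabolite, strong but within the range seen for metabolite
quantitative trait loci — plus two effect-free genes as negative controls.

**Missingness** is missing-completely-at-random only. Real metabolomics
missingness is partly concentration-dependent (left-censored); passing the
imputation tests here says nothing about MNAR behaviour.

**What passing tests do and do not show.** The generator is linear-Gaussian
with faithful parameterizations *in distribution*; finite parameter draws
can still near-cancel. Real metabolomes add nonlinearity, measurement-batch
structure, and latent confounding that the generator does not emulate, so
structure-recovery rates reported here are upper bounds on what to expect
from real cohort data.

## Preprocessing

Order: **filter → impute → transform → adjust**. Metabolites with ≥ 50% missing
values are excluded *before* imputation (the rule must see the original
missingness pattern), together with metabolites that no candidate transform
renders acceptably normal. Imputation is k-nearest-neighbour by default
(k = 10, Euclidean distance over metabolites complete in the matrix), with
half-minimum and column-median options for sensitivity. The transform
search maximizes the Shapiro–Wilk W over {identity, log, √, square}; log
and √ are skipped (not shifted) for non-positive data, because shift
constants are arbitrary and move the winner. W is computed on at most 5000
points (deterministic evenly spaced order-statistic subsample above that).
The acceptance threshold defaults to W ≥ 0.90 and is configurable since no
universal criterion exists; the default is deliberately tolerant because a
genuine carrier-shift mixture — a metabolite moved 1.5 SD in the 8% of
samples carrying a LoF allele, squarely the effect the pipeline exists to
find — already fails W ≥ 0.95 at n = 2000, while heavy-tailed or otherwise
untransformable columns still fall below 0.90. Covariate adjustment is per-metabolite OLS on all
covariates plus intercept; residuals are orthogonal to every covariate at
machine precision and the operation is idempotent.

## Variant selection

The scan computes every unit × metabolite simple regression in closed form
(vectorized correlation algebra, identical to `lm` to 10⁻¹⁰). The
family-wise threshold is $\alpha/(n_\text{met} \times n_\text{var})$; with
122 metabolites and 372 (respectively 451) LoF variants this gives
1.10×10⁻⁶ (9.09×10⁻⁷). The penalized route fits all units jointly by
lasso over the tuning grid {1.5, 0.3, 0.01}, refits each support by OLS,
and keeps the minimum-BIC support (ties → smaller support). BIC is computed
on the OLS refit because the penalized fit's biased coefficients make its
likelihood scale-dependent. The published convex–concave penalty this
stands in for is defined in work we do not reproduce; the lasso keeps the
quoted behaviour (joint model, sparsity, small tuning grid, min-BIC) and
the interface leaves room to swap the exact penalty in later. Replication
re-tests selected pairs on an independent sample with Bonferroni over the
replication family.

## Instruments

Proxy clustering is average-linkage hierarchical clustering on
$1 - |r|$, cut at height $1 - 0.80$; unsigned correlation because allele
coding is arbitrary. The cluster representative is the highest-MAF variant
(ties → lowest position), recorded in the proxy map for audit. PCA runs on
the correlation (standardized) scale so allele-frequency differences do not
dominate loadings; the smallest leading set of components explaining
*more than* 90% of variance is retained. Scores are re-standardized, which
keeps instrument columns exactly orthogonal.

## Network learning

The conditional-independence test is the Gaussian partial correlation with
the Fisher z transform — metabolites are transformed toward normality
upstream, which is what makes this test appropriate. The skeleton search is
the order-independent ("stable") PC variant, with the inner loop in
compiled code. Two pieces of background knowledge shape the search:

* Instrument–instrument edges are excluded a priori (principal components
  are orthogonal by construction).
* For a metabolite–metabolite pair, conditioning candidates are restricted
  to adjacent *metabolites*. Instruments are exogenous sources whose
  influence enters through their target metabolites, so any separable
  metabolite pair is separable within the metabolite layer; allowing
  near-deterministic combinations of genetic scores into those conditioning
  sets empirically removes true metabolite edges through spurious
  near-independences.

Orientation proceeds in three stages. (1) Instrument edges are anchored
instrument → metabolite. (2) Unshielded triples are classified by a
**supermajority vote**: all conditioning subsets (size ≤ 5) of the two
adjacency sets are enumerated, and the triple is a collider when fewer than
25% of the separating subsets contain the middle node, a non-collider when
more than 75% do, and *ambiguous* otherwise. Ambiguous triples are left
unoriented and block the first Meek rule, so weak or conflicting evidence
never forces a direction. This blend of conservative and majority-rule
collider handling was adopted because trusting the single first-found
separating set — the textbook rule — reverses a substantial fraction of
edges whenever overlapping pathways nearly cancel, which random effect
signs make common. (3) Meek rules R1–R4 propagate orientations;
orientations that would point into an instrument or reverse an existing
arrow are dropped and logged as conflicts. Finite-sample conflicts can
leave a directed cycle; the network constructor warns and records a flag
rather than failing, so replicate studies run to completion.

Level tuning interprets "best fit by SHD over replicates" as *subsample
stability*: the same 45 random 80% subsamples are analysed at every
candidate level and each level is scored by the mean pairwise SHD among its
45 networks; the most stable level wins, ties toward the smaller level. On
the study generator this selects 0.001 most often, and its skeleton F1 sits
within 0.02 of the best grid point on average.

## SEM and pleiotropy

Estimation is equation-by-equation OLS (path analysis): consistent and
asymptotically equivalent to full-information ML for a recursive
linear-Gaussian system, without the optimizer fragility. Stage 1 regresses
each metabolite on its directed metabolite parents; stage 2 regresses the
stage-1 residual on all tested gene burdens jointly. With no metabolite
edges the procedure reduces *exactly* to the marginal scan — a useful
end-to-end identity test. Undirected edges incident to a fitted metabolite
raise an error by default (`undirected = "ignore"` treats them as absent,
which the pipeline uses and reports); fitting both orientations is a
sensitivity analysis the caller can run by orienting the edge each way.
Verdicts use a per-gene Bonferroni at level 0.05 over the gene's candidate
metabolites (no level is canonical for this stage); `direct` needs the
conditional γ to survive it, `mediated` needs a directed path from a direct
target, and the gene is pleiotropic with ≥ 2 direct verdicts.

## Modules

Greedy modularity maximization on the undirected metabolite skeleton
(deterministic), followed by a coarsening pass that merges communities
while modularity does not decrease — this breaks numerical ties toward the
coarsest partition so a single clique is one module. A `resolution`
argument switches to Leiden optimization of modularity under a fixed
internal seed for non-default resolutions. The number of modules is always
an output, never an input.

## Numerical choices and degenerate inputs

* Partial correlations clamp to ±(1 − 10⁻¹²) before `atanh`; singular
  conditioning submatrices fail the test (edge retained) in the search and
  raise an error in the user-facing test.
* The Fisher z test requires n > |S| + 3; the search stops growing
  conditioning sets at that bound.
* Monomorphic variants: flagged and retained by the generator (with a
  warning), skipped by the scan, correlation 0 in the LD matrix, excluded
  from instruments.
* BIC ties in penalized selection break toward the smaller support;
  stability ties in level tuning break toward the smaller level;
  representative ties in proxy clustering break by position then id.
* All simulation functions take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical outputs, and a pipeline
  bundle rerun under the same configuration is byte-identical.

## Problem sizes used by the test-suite and the acceptance script

Structure recovery: 20 seeds (tests) / 10 seeds (script) at n = 2000.
Tuning: 5 / 3 seeds × 45 replicates × 5 levels. SEM recovery: 100 / 50
seeds at n = 5000. Pleiotropy verdicts: 200 / 100 replicates per scenario
at n = 2000. Scan error control: 500 / 300 null replicates of the
122 × 372 scan at n = 1500. These sizes keep each quantity's Monte-Carlo
error well inside the margins being asserted.

## Known limitations

* Linear-Gaussian CI tests only; monotone-nonlinear dependence is diluted.
* No latent-confounder discovery: hidden common causes of two metabolites
  appear as directed or undirected edges, not bidirected ones.
* MCAR missingness only, and the k-NN imputation assumes informative
  between-sample distances.
* The penalized-selection route is a lasso stand-in for the published
  convex–concave selector; supports may differ in strongly correlated
  designs.
* Pleiotropy verdicts inherit network errors: a missed metabolite edge can
  turn a mediated effect into an apparent direct one.
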