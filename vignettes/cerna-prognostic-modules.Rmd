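---
title: "ceRNA network inference and prognostic module discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNA network inference and prognostic module discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cernasurv` implements a complete competing-endogenous-RNA (ceRNA) analysis
pipeline: from an expression matrix, a miRNA-target map and a seed-gene list
to scored ceRNA pairs, a seed-anchored network, overlapping k-clique modules
and survival-prognostic module risk scores. This vignette documents the
statistical model behind each stage, the tunable parameters, the synthetic
data generator used to validate the pipeline, and the design decisions taken
where the methodology was genuinely open.

## The ceRNA model and the two-stage pair filter

The ceRNA hypothesis is that two RNAs regulated by many of the same miRNAs
compete for those miRNAs and are therefore co-regulated. A candidate pair
must satisfy two criteria simultaneously.

**Shared-miRNA significance.** For RNAs A and B targeted by $K$ and $M$
miRNAs out of a universe of $N$, the probability of observing at least $x$
shared regulators by chance is the hypergeometric upper tail

$$P = 1 - F(x \mid N, K, M) = 1 - \sum_{t=0}^{x-1}
  \frac{\binom{K}{t}\binom{N-K}{M-t}}{\binom{N}{M}}.$$

`hyper_shared_pval()` evaluates this through the survival function of
`stats::phyper()`, which works in log space and is stable for realistic
universes ($N$ in the hundreds); it is verified in the test suite against
exhaustive enumeration of all $\binom{N}{M}$ draws for every $N \le 12$.
Pairs are kept when $x \ge 3$ **and** the Benjamini-Hochberg adjusted
p-value is below 0.01. The universe $N$ is defined as the number of
distinct miRNAs in the merged miRNA-mRNA + miRNA-lncRNA map — the only
closed universe the input data defines.

**Co-expression.** Surviving pairs must also show strong co-expression:
Pearson correlation of the log2 expression with $|\rho| > 0.5$ and BH-FDR
below 0.01 (two-sided t-test, $n-2$ df). The absolute-value threshold is
the default because the screening rule is usually stated that way, even
though the ceRNA mechanism itself predicts positive correlation;
`positive_only = TRUE` enforces $\rho > 0.5$.

Two deliberately open points are parameterised rather than hard-coded:

* **FDR families.** The correlation FDR is computed over the stage-1
  survivors only (`fdr_scope = "sequential"`, the default, mirroring a
  pipeline where stage 1 "reserves" pairs for stage 2); `"global"` adjusts
  across every enumerated pair instead. Both are exposed because the choice
  of family is not derivable from the method's usual description.
* **Pseudocount.** The zero-fraction filter keeps genes with up to 50% zero
  entries, so the log2 transform uses `log2(x + 1)`; a bare log would be
  undefined on retained data.

Pairs sharing zero miRNAs are never enumerated: an inverted index over the
target map (a sparse RNA-by-miRNA incidence matrix and its cross-product)
yields exactly the pairs with $x \ge 1$, which provably gives the same
result as a quadratic scan under the $x \ge 3$ filter at a fraction of the
cost.

## Preprocessing

RNAs with expression exactly zero in *strictly more than* half the samples
are removed (`filter_expression()`, boundary kept), then values are log2
transformed with pseudocount 1 (`log2_transform()`). The expression
container records its preprocessing state so each step can only be applied
once and in order; pair scoring refuses untransformed input.

## Seed subnetwork and topology

`extract_seed_subnetwork()` induces the subgraph on the seed ("ageing")
genes plus their direct neighbours and keeps its largest connected
component — the maximal connected component of the *sub*network, not of the
full graph. Size ties are broken by the lexicographically smallest member
set so the result is deterministic.

Centralities (`network_centralities()`) are computed on the unweighted
graph: degree; closeness $CC(v) = 1/\sum_{j \ne v} d(v,j)$ over reachable
$j$, with $CC = 0$ for isolated nodes by convention; and betweenness.
Betweenness is offered in two variants. The default is the standard
fraction form $\sum_{s \ne t \ne v} \sigma_{st}(v)/\sigma_{st}$, what
igraph and Cytoscape report. The `bc = "raw"` variant sums the raw path
counts $\sigma_{st}(v)$ without the denominator — a form that sometimes
appears in print, almost certainly as a typographical simplification; both
are cheap to provide and both are validated against brute-force
shortest-path enumeration. The raw variant materialises all-pairs path
counts and is intended for networks up to a few hundred nodes.

Group comparisons (seed genes vs their ceRNAs) use the two-sided
Mann-Whitney rank test: centrality distributions are heavily right-skewed,
so a rank test is the defensible default when the testing procedure is not
otherwise specified.

Degree distributions are summarised by a least-squares line on
$\log_{10}$ frequency vs $\log_{10}$ degree over nonzero bins — the usual
visual power-law check, not a maximum-likelihood tail fit (see
Limitations). Hub extraction keeps the $\lfloor 0.10\,|V| \rfloor$
highest-degree nodes (a 1322-node network yields exactly 132 hubs), with
lexicographic tie-breaking at the boundary.

## k-clique percolation modules

`k_clique_communities()` implements classic clique percolation: two
k-cliques are adjacent when they overlap in $k-1$ nodes, and a community is
the node union over a connected chain of such cliques. The implementation
works on *maximal* cliques of size $\ge k$ (Bron-Kerbosch enumeration via
igraph) with overlap threshold $k-1$ — the standard optimisation, provably
equivalent to enumerating all k-cliques. `discover_modules()` repeats this
for every $k$ from `k_min` (default 11, i.e. "k > 10") up to the largest
clique, naming modules `K{k}M{index}`.

Because the internal numbering of the original CFinder tool is not
documented, indices here are assigned by community size (descending), ties
by lexicographically smallest member set: deterministic and reproducible,
but module *labels* are not comparable across implementations. A
maximal-clique budget (default $5 \times 10^6$) guards against
pathologically dense graphs.

## Survival analysis

For each module, a multivariate Cox proportional-hazards model is fitted
with the module genes as covariates (`survival::coxph`, Efron ties,
tolerance $10^{-9}$, up to 100 iterations). The module risk score of a
sample is the linear predictor

$$RS = \sum_{i=1}^{n} R(i)\,\mathrm{Exp}(i),$$

with $R(i)$ the fitted coefficient and $\mathrm{Exp}(i)$ the log2
expression. Samples with $RS$ strictly greater than the mean $RS$ of the
*training* samples are high risk; the same threshold dichotomises the test
set. Two ambiguities are parameterised:

* **Fitting cohort.** Coefficients are fitted on the training half by
  default (no information leaks into the test-set evaluation);
  `paper_mode = TRUE` fits on all samples, matching pipelines that describe
  the risk score as derived from the full cohort.
* **Threshold cohort.** The training-mean threshold is the default (the
  common convention "the average risk score of the training set divides
  both sets"); passing `train = NULL` to `risk_scores()` uses the
  all-sample mean instead.

The cohort split is a seeded uniform partition with the extra sample on an
odd cohort going to the test set (251 samples split 125/126). Prognosis is
assessed by Kaplan-Meier curves and the two-sided log-rank test in the
training *and* the test set; a module passes the screen only when both
p-values are below `alpha` (default 0.05). Discrimination is measured by a
cumulative-case/dynamic-control time-dependent ROC AUC with
inverse-probability-of-censoring weights from the Kaplan-Meier estimate of
the censoring distribution, evaluated at the left limit of each case's
event time; the default horizon is the median follow-up, `horizon`
overrides. An optional ridge penalty (`ridge`, default 0) is exposed
because a 12-16 gene Cox model on ~125 training samples with strongly
co-expressed covariates can be unstable; fits that fail to converge error
with a suggestion to use it.

A Table-1 style analysis (univariate Cox for risk score, gender, age, and
one multivariate model with all three) is attached per module and per set.
Gender is coded with female as the reference level; this is configurable
by recoding the input column.

## The synthetic study generator

`simulate_cerna_study()` generates the full input bundle — target map,
expression, clinical table, seed list — plus a ground-truth ledger, so the
whole pipeline can be validated end to end. The model:

* **Target map.** Each planted module receives a disjoint block of
  `mirnas_per_module` miRNAs targeting every module gene, so within-module
  pairs share the entire block by construction. All remaining RNAs draw
  `background_targets_per_rna` targets uniformly. The first module
  contains one lncRNA member, mirroring the mixed mRNA/lncRNA modules seen
  in real ceRNA networks.
* **Expression.** Latent activity model on the log2 scale: miRNA $m$ has
  per-sample activity $a_{ms} \sim N(0,1)$ and
  $L_{gs} = \mu_g - w \sum_{m \in T(g)} a_{ms} + \varepsilon_{gs}$ with
  $\mu_g \sim U(4, 9)$ and noise SD `noise_sd`. The RPKM-like value is
  $\max(2^{L} - 1, 0)$, so the pipeline's $\log_2(x+1)$ transform inverts
  the link exactly wherever $L \ge 0$. Two RNAs sharing $s$ of their
  regulators have latent correlation $s\,w^2 / \sqrt{(K w^2 + \sigma^2)(M
  w^2 + \sigma^2)}$ — the closed form the calibration tests check. A
  `zero_inflation` fraction of entries (default 0.02) is zeroed uniformly,
  emulating residual dropout in RPKM data that has already passed a
  zero-fraction filter; the default is kept small because heavy masking of
  high-expression genes would not survive that filter in real data and
  visibly attenuates pairwise correlations.
* **Survival.** Event times are exponential with rate
  $h_0 \exp\{\sum_i \beta_i (\mathrm{Exp}_i - \bar{\mathrm{Exp}}_i)\}$
  over the prognostic module's genes (centred so `baseline_hazard` keeps
  its interpretation). The per-gene coefficients alternate
  $\pm$`beta_surv`. This sign pattern is a deliberate identifiability
  choice: module genes share a common latent factor (correlation
  $\approx 0.95$ under the defaults), and with alternating signs the
  common factor cancels from the linear predictor, so each coefficient is
  identified through that gene's independent noise — a Cox refit on the
  true module then recovers the coefficient signs, which a uniform-sign
  design with this much collinearity would not allow. Censoring is
  independent $U(0, c)$ with $c$ solved by root finding so the expected
  censored fraction equals `censor_rate`; follow-up times are strictly
  positive by construction (the readers still validate this on arbitrary
  input). Age and gender are generated with zero true hazard effect,
  giving the Table-1 comparisons a known null.
* **Seeds.** One designated member per planted module plus random
  background mRNAs, so every planted module lies inside a seed gene's
  direct neighbourhood.

The default configuration is the "strong" study preset used throughout the
validation suite: 300 samples, 1800 mRNAs + 200 lncRNAs, 150 miRNAs, four
planted 12-gene modules (5 miRNAs each), repression weight 1, noise SD 0.5,
`beta_surv` 1 on module 1 only, 30% censoring. Everything is seeded:
identical configurations reproduce bit-identical studies.

**What the generator does not emulate.** Planted modules use disjoint
miRNA blocks, so the synthetic ceRNA network has one connected component
per module; after the maximal-connected-component step the seed subnetwork
therefore contains a single module per run, and multi-module screens in
the tests operate on the full ceRNA network instead. There is no negative
binomial count noise, no library-size variation, no batch effects and no
competing risks. Passing tests therefore demonstrate correctness of the
inference machinery under the stated model, not robustness to every
artefact of real RNA-seq cohorts.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant expression vectors make
a pair's correlation undefined (the pair is dropped with a warning; the
scalar `pearson_test()` errors); an all-degenerate matrix errors at the
filter; empty module lists simply skip the survival stage; zero-event
cohorts and single-group splits error with informative messages.
Deterministic tie-breaks are used everywhere ordering matters
(lexicographic node ids for hubs and clique orderings, smallest member set
for component and module ties) so identical inputs give byte-identical
outputs.

The validation suite runs oracles at sizes where exhaustive enumeration is
exact: hypergeometric universes to $N = 12$, centralities on 200 random
graphs of up to 25 nodes, clique percolation on 100 random graphs of up to
18 nodes, Cox parameter recovery at $n = 1000$ over 200 replicates,
log-rank calibration over 1000 null replicates, and 20 end-to-end
replicates of the strong preset. These sizes give the calibration
assertions comfortable Monte-Carlo margins while keeping the whole suite
inside a couple of minutes.

## Limitations

* The power-law summary is an ordinary least-squares fit on log-log binned
  frequencies — adequate as the conventional visual check, but not a
  Clauset-Shalizi-Newman maximum-likelihood tail estimate.
* Predicted (non-validated) miRNA targets, partial-correlation ceRNA
  scores and miRNA expression data are out of scope: the pair test uses
  target-map membership and co-expression only.
* The raw-count betweenness variant is quadratic per node and intended for
  moderate graphs.
* No proportional-hazards diagnostics or competing-risk models are
  provided; the Cox stage assumes the standard PH model.
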