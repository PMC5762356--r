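# cernasurv

Competing endogenous RNA (ceRNA) network inference and prognostic module
discovery in R.

## The problem

mRNAs and long non-coding RNAs that share miRNA response elements compete
for the same miRNA pool; such **ceRNA pairs** de-repress one another and are
positively co-expressed. Networks built from these pairs — anchored on a
curated seed list such as ageing-associated genes — expose densely
co-regulated modules whose joint expression can stratify cancer patients by
survival. `cernasurv` implements this analysis as a tested, reusable
pipeline for anyone working with an expression cohort (RPKM-like values), a
validated miRNA-target map and right-censored clinical follow-up.

## The method

For every RNA pair A, B with regulator counts *K*, *M* out of a study
universe of *N* miRNAs and *x* shared regulators, the shared-miRNA
significance is the hypergeometric upper tail

> P = 1 − F(x | N, K, M) = 1 − Σ<sub>t&lt;x</sub> C(K,t)·C(N−K,M−t) / C(N,M),

and a pair is a ceRNA candidate when **x ≥ 3 and BH-FDR(P) < 0.01** and,
on the log2-transformed expression, **|Pearson ρ| > 0.5 with BH-FDR <
0.01**. The seed-gene subnetwork (seeds plus their direct neighbours,
maximal connected component) is analysed topologically (degree, closeness,
betweenness, hub decile, power-law degree fit), decomposed into overlapping
modules by **k-clique percolation** (k ≥ 11 by default, modules named
`K{k}M{index}`), and each module is scored per sample as

> RS = Σ<sub>i</sub> R(i) · Exp(i),

where R(i) are multivariate Cox coefficients of the module genes. Samples
above the training-set mean RS are high risk; a module is prognostic when
the two-sided log-rank test separates high from low risk in **both** the
training and the test half, with discrimination measured by an IPCW
time-dependent ROC/AUC. A seeded synthetic-study generator with a full
ground-truth ledger backs the entire validation suite.

## Worked example

```r
library(cernasurv)

study <- simulate_cerna_study(sim_config(seed = 42))   # 300 samples, 2000 RNAs
expr  <- study$expr |> filter_expression() |> log2_transform()
pairs <- score_candidate_pairs(expr, study$tmap)
pairs[1:3, c("rna_a", "rna_b", "x", "K", "M", "q_hyper", "rho", "q_corr")]
#>   rna_a  rna_b      x     K     M     q_hyper   rho   q_corr
#> 1 G00021 G00327     5     5     5 0.000000780 0.884 1.16e-98
#> 2 G00021 G00567     5     5     5 0.000000780 0.771 3.83e-60
#> 3 G00021 G00593     5     5     5 0.000000780 0.795 2.40e-66
```

266 pairs pass both filters. Build the network, extract the seed-anchored
component and discover k-clique modules:

```r
net    <- build_cerna_network(pairs, classes = expr_classes(expr),
                              seeds = study$seed_genes)
agenet <- extract_seed_subnetwork(net, study$seed_genes)
modules <- discover_modules(net, k_min = 11)
modules[, c("name", "k", "size")]
#>   name      k  size
#> 1 K11M1    11    12
#> 2 K11M2    11    12
#> 3 K11M3    11    12
#> 4 K11M4    11    12
#> 5 K12M1    12    12
#> ...
```

Screen the k = 11 modules for prognostic ability (Cox fit on the training
half, log-rank in both halves, time-dependent AUC at the median follow-up):

```r
screen <- prognostic_screen(modules[modules$k == 11, ], expr,
                            study$clinical, seed = 42)
tidy(screen)
#>   module     k  size logrank_p_train logrank_p_test auc_train auc_test passes
#> 1 K11M3     11    12        1.14e-25       1.79e-27     0.913    0.922 TRUE
#> 2 K11M2     11    12        2.92e- 1       1.18e- 1     0.603    0.546 FALSE
#> 3 K11M1     11    12        1.58e- 4       4.21e- 1     0.743    0.483 FALSE
#> 4 K11M4     11    12        1.46e- 1       7.14e- 1     0.624    0.505 FALSE
```

Exactly one module passes in both cohort halves — it is the module the
generator planted with a survival signal (`study$ground_truth`), recovered
with train/test AUCs of 0.91/0.92; the three null modules fail the screen.
The miRNAs shared by the passing module's ceRNA pairs are ranked by
`module_mirna_regulators()`; each of the module's 66 internal pairs shares
the five planted regulators:

```r
module_mirna_regulators(modules$members[[3]], pairs, tmap = study$tmap)$top
#>   mirna    pair_count
#> 1 miR-0011         66
#> 2 miR-0012         66
#> ...
```

`autoplot()` methods draw the Kaplan-Meier curves, ROC curves and degree
distributions; `run_cerna_pipeline(pipeline_config(...))` executes every
stage against files on disk and writes TSV/GraphML/JSON artifacts plus a
reproducible run manifest, and `inst/cli/cernasurv.R` wraps simulation,
input validation and the full run as a command-line tool.

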