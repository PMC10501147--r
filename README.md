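# pnimeta

Multi-cohort differential-expression meta-analysis for cancers with
perineural invasion (PNI).

Solid tumors with high nerve density — pancreatic, head-and-neck,
gastric, and others — recruit nerves and metastasize along them. A
recurring observation in transcriptomic studies of these cancers is
that *pathways*, not individual genes, are the conserved unit of
dysregulation: different cohorts and different cancers disrupt the same
axon-guidance pathway through different paralog genes (one cohort
upregulates EFNA5, another EFNB2, yet the ephrin pathway is hit in
both). Testing that hypothesis requires a pipeline that (i) calls
differentially expressed genes (DEGs) consistently across many
microarray cohorts, (ii) checks that calls from unbalanced cohorts are
not artifacts of group composition, (iii) intersects calls within and
across cancers, (iv) cross-references them against neurodevelopmental
gene signatures and collapses them into paralog families, and (v) asks
whether the implicated genes and families stratify patient survival.

`pnimeta` implements that pipeline for R users analyzing GEO-style
series-matrix cohorts, together with a synthetic-data generator that
plants known truth (true DEGs, a cross-cancer core, paralog-family
effects, expression-linked hazards) so every stage is testable without
any download.

## The statistics at the core

**Moderated t.** For each probe g, with tumor/control group means and
pooled residual variance s²_g on d_g = n_T + n_C − 2 degrees of
freedom, the per-probe variances are shrunk toward a common prior
s₀² with d₀ prior degrees of freedom, estimated by the method of
moments on e_g = log s²_g − ψ(d_g/2) + log(d_g/2):

    trigamma(d₀/2) = mean[(e_g − ē)² · G/(G−1) − ψ′(d_g/2)]   (Newton inversion)
    s₀² = exp(ē + ψ(d₀/2) − log(d₀/2))
    s²_post = (d₀ s₀² + d_g s²_g) / (d₀ + d_g)
    t_g = log2FC_g / (s_post √(1/n_T + 1/n_C)),  df = d₀ + d_g

p-values are BH-adjusted; a gene is a DEG when |log2FC| ≥ 1 and
adjusted p < 0.05 (both thresholds configurable, including the ≥ vs >
boundary convention). When several probes map to one gene, all probes
are used and the gene is called through its best qualifying probe.

**Equalization.** For cohorts with unbalanced tumor/control counts,
the larger group is repeatedly (default 100×) subsampled to the
smaller group's size, DEGs are re-called each time at identical
thresholds, and per-gene frequencies quantify robustness to the
imbalance.

**Meta-intersection.** Within a cancer, genes recurring as DEGs in at
least k (default 3) cohorts survive; across cancers either these
survivors (`qualified`) or the per-cancer unions (`any_dataset`) are
intersected, with genes up in one cancer and down in another classed
`mixed`.

**Signatures, families, enrichment.** DEG lists are cross-referenced
against GMT signatures (overlap fraction with the DEG count as
denominator), collapsed into paralog families (a family is dysregulated
in a cancer iff ≥ 1 member is a DEG in ≥ 1 cohort), and tested for GO
term over-representation with the hypergeometric upper tail and BH
adjustment.

**Survival.** Kaplan–Meier curves, two-group log-rank, univariate Cox
(Breslow ties; low-expression group as reference, so HR > 1 means
higher expression carries worse survival), combined paralog scores
(mean of median-centered per-gene expression), and a best-cutoff scan
that minimizes the log-rank p over admissible score cutoffs. Because
minimizing p over cutoffs inflates type-I error, a patient-permutation
adjusted p is computed alongside the nominal minimum.

## Worked example

Simulate a study-scale collection (3 cancers × 4/4/5 cohorts, an
18-gene cross-cancer core, 17 paralog families, a signature holding
47% of planted DEGs), then run the stages:

```r
library(pnimeta)
cfg  <- sim_config()
coll <- gen_cancer_collection(cfg, seed = 1)
coll <- gen_signature_and_families(coll, cfg, seed = 2)

de_analyze(coll$datasets$cancerA$cancerA_ds1)
#> DE result [cancerA_ds1]: 3967 probes, 2000 genes
#>   thresholds: |log2FC| >= 1, adj p < 0.05
#>   eBayes prior: d0 = 1.03e+03, s0^2 = 0.2512
#>   DEGs: 167 genes (86 up, 81 down, 0 discordant)

de <- lapply(coll$datasets, function(cc) lapply(cc, de_analyze))
cross_cancer_intersect(de, mode = "qualified")
#> Cross-cancer intersection (qualified mode): 18 genes
#>   down: 1, mixed: 16, up: 1

all_degs <- unique(unlist(lapply(de, function(cc) lapply(cc, deg_genes))))
crossref_signature(all_degs, coll$truth$signature)
#> Overlap with 'NDEV_SIM': 296 of 629 DEGs (47.1%)

family_collapse(de, coll$truth$family_map)
#> Family status: 17 families x 3 cancers
#>   dysregulated in all cancers: 17 (FAM01, FAM02, FAM03, ...)
```

The 18 recovered genes are exactly the planted core, the 47.1% matches
the planted signature overlap, and all 17 planted families are found
dysregulated in every cancer even though each cohort expresses the
family effect through a different member.

Survival stratification by a combined two-paralog score, with the
planted log-hazard ln 2 on one member:

```r
g  <- gen_survival_cohort(300, c("EFNA1", "EFNA5"),
                          beta = c(EFNA5 = log(2)), seed = 3)
sc <- best_cutoff_scan(g$cohort,
                       gene_score(g$cohort, c("EFNA1", "EFNA5")),
                       n_perm = 1000, seed = 4)
sc
#> Best-cutoff scan: 241 candidates
#>   best cutoff 0.6632 (low 249 / high 51), log-rank p = 7.768e-07
#>   permutation-adjusted p (1000 perms): 0.001998
#>   Cox at best split: HR = 2.308 (95% CI 1.641-3.247)
```

Real cohorts enter through `read_series_matrix()` (GEO series-matrix
dialect, with a user-supplied `group_rule()` mapping a characteristics
field to tumor/control), `read_gmt()` for signatures, and
`read_table_map()` for probe annotation and paralog-family tables.

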