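---
title: "Methods: multi-cohort DEG meta-analysis, paralog families and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort DEG meta-analysis, paralog families and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnimeta)
```

This vignette is the package's own account of its statistical methods:
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate,
and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Differential expression

### Model

Each cohort is a probe × sample matrix of log2 intensities with
tumor/control labels. Per probe the two-group fit gives the mean
difference (the log2 fold change on log-scale data), the pooled
residual variance $s_g^2$ on $d_g = n_T + n_C - 2$ degrees of freedom
and the scale factor $v_g = 1/n_T + 1/n_C$. Missing cells are handled
pairwise-complete: each probe uses its own complete observations per
group with $d_g$ reduced accordingly, and probes with fewer than two
complete values in either group are dropped (the count is reported).
This assumes values are missing unrelated to group and expression
level, which is adequate for scattered platform missingness but not
for intensity-dependent censoring.

Variances are moderated by the standard empirical-Bayes
scaled-inverse-chi-square prior. Writing
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the prior degrees of
freedom solve

$$\psi'(d_0/2) \;=\; \operatorname{mean}\Big[(e_g-\bar e)^2
\tfrac{G}{G-1} - \psi'(d_g/2)\Big],$$

by Newton inversion of the trigamma function, and
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. Posterior
variances $(d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$ give the moderated t on
$d_0 + d_g$ degrees of freedom. Two limits are exposed directly:
`prior_df = 0` reduces to the ordinary pooled t (the test suite checks
equality with an independent `t.test()` implementation to 1e-12), and
`prior_df = Inf` pools all probes into one variance. The finite-$d_0$
path is cross-checked against `limma::eBayes` to 1e-8 in the tests;
the implementation itself is the package's own.

Numerical details: the trigamma inversion starts from the asymptotic
inverses ($1/\sqrt{x}$ for large $x$, $1/x$ for small $x$), iterates at
most 50 Newton steps to a relative tolerance of 1e-10, and when the
moment target is non-positive the prior is degenerate
($d_0 = \infty$, every probe shares $\exp(\bar e)$ — this is the
common case for the homoscedastic generator below). Probes with zero
sample variance are excluded from hyperparameter estimation; if all
variances are zero the input is degenerate and an error instructs
adding noise. Fewer than 10 usable probes triggers a fallback to the
ordinary t with a warning.

### DEG thresholds

`de_thresholds()` holds `lfc_min` (default 1, log2 units), `adj_p_max`
(default 0.05, after BH adjustment) and the boundary convention.
Methods sections and figure captions of microarray studies routinely
disagree on whether the fold-change boundary is inclusive; both are
supported and `>=` is the default. They differ only for effects
landing exactly on the boundary.

### Gene-level collapse

All probes of a gene are used. A gene is a DEG when at least one
annotated probe passes both thresholds. The reported gene-level
statistics come from one representative probe: for DEGs the *passing*
probe with the smallest adjusted p (ties: larger |log2FC|, then
lexicographic probe id); for non-DEGs the best probe overall.
Restricting the representative to passing probes keeps the invariant
that a DEG's direction equals the sign of its reported log2FC. Genes
whose passing probes disagree in sign are flagged `discordant` — they
stay in the table but are excluded from direction-classified output
and from the meta-intersection, since a direction cannot be assigned
honestly.

## 2. Equalization resampling

For unbalanced cohorts, each of `n_repeats` (default 100, the
conventional choice for this procedure) repeats subsamples the larger
group without replacement to the smaller group's size, re-runs the
complete DE stage at identical thresholds, and tabulates per-gene DEG
frequencies. Repeats are independent; the subsampled id sets are
logged and reproducible from the seed, and ids (not column positions)
are drawn so results are invariant to sample order. A "robust" DEG is
one called in at least `robust_frac` (default 50%) of repeats — the
reporting threshold is this package's choice, as frequency tables
alone do not define a cutoff — and the headline summary is the
fraction of reference DEGs that are robust. The reference defaults to
the same dataset's full-data call (the within-dataset comparison);
whether the procedure should be scored within-dataset or against other
cohorts' calls is genuinely ambiguous, so both are supported via the
`reference_degs` argument, with within-dataset the default because it
isolates the effect of composition from cohort-to-cohort
heterogeneity. An optional `restriction_list` reruns the tabulation on
the probes of a supplied gene list, mirroring the two-pass design of
running first on all probes and then only on the recurrent ones.
Balanced input degenerates gracefully: every repeat uses the full
data.

## 3. Meta-intersection

Within a cancer, a gene survives when it is a concordant DEG in at
least `k_min` (default 3) cohorts. Across cancers, `qualified` mode
intersects these survivors; `any_dataset` mode intersects the
per-cancer unions. The two scopes answer different questions
(recurrence-filtered consensus vs any-evidence overlap) and both are
kept, with the scope recorded on the result. Direction classes are
derived from all supporting datasets: `mixed` iff both signs occur.
Raising `k_min` can only remove genes, and `qualified` output is a
subset of `any_dataset` output; both properties are tested.

## 4. Signatures, paralog families, enrichment

Signature overlap is a set intersection on normalized (upper-cased,
deduplicated) symbols; the reported fraction always uses the DEG count
as denominator. An empty DEG list yields a missing, not zero,
fraction. Declared sizes of imported signatures (GMT descriptions) are
stored as provenance only — annotation databases drift, so no
computation may depend on them.

A paralog family is dysregulated in a cancer iff at least one member
is a DEG in at least one cohort of that cancer; supporting (gene,
cohort, direction) triples are retained so the
different-paralog-per-cohort pattern remains queryable. This collapse
is monotone (adding DEGs never removes a family).

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ computed via the log-space distribution function, BH
adjustment across tested terms, both raw and adjusted thresholds at
0.05, and ranking by overlap count, then gene ratio, then term id.
The q-value threshold used by common GO tools is approximated by the
BH-adjusted p: it is monotone in the same statistic and keeps the
package dependency-free; the numbers differ from a Storey q-value by
the null-proportion estimate. The universe defaults to all annotated
genes and should be set to the platform's annotated genes when DEGs
were called per platform — whether a platform-restricted universe is
the right choice is itself an analysis decision the caller controls.

## 5. Clustering QC

Quantile normalization (the standard limma implementation, tie-aware)
is available but off by default — series matrices usually arrive
preprocessed, so normalization is applied only "when needed", under an
explicit flag. Samples are clustered with multi-start Lloyd k-means on
the `n_top = 2000` most variable probes (the feature space is not
dictated by the data format; 2,000 covers the high-variance structure
at typical platform sizes while keeping distances stable). The
within-group sum-of-squares curve over $k = 1..k_{max}$ is reported
with an elbow estimate (maximum second difference), but the
tumor/control question is always answered at $k = 2$ with the adjusted
Rand index against the labels (0 by convention at $k = 1$). Each $k$
is additionally warm-started from the best $k-1$ solution with its
widest cluster split, which guarantees a non-increasing WSS curve —
plain independent restarts do not.

## 6. Survival

Kaplan–Meier estimation and the univariate Cox model delegate to the
`survival` package (Breslow tie handling; 50 iteration cap). The Cox
wrapper flags monotone partial likelihood and reports the affected
confidence bound as unbounded. The HR convention follows forest-plot
practice: the low-expression group is the reference, so HR > 1 with
p < 0.05 is classified `worse-when-high` and HR < 1 `better-when-high`.

The two-group log-rank statistic is implemented in the package itself,
vectorized over many group splits at once, because the best-cutoff
scan evaluates hundreds of splits and the permutation adjustment
thousands; `survival::survdiff` agrees with it to 1e-10 in the tests
and serves as the independent oracle.

Combined paralog scores default to the mean of median-centered
per-gene values — median centering is robust to skewed expression and
the unweighted mean does not privilege any paralog; a z-score variant
is available when variance differences between paralogs should be
equalized. The cutoff scan considers every distinct score value whose
split leaves at least `min_group_frac = 0.1` of patients on each side
(external cutoff-selection tools do not document their grid; the
10th–90th percentile bound is this package's declared choice, not a
reproduction), takes the minimal log-rank p (ties resolved toward the
median, then the smaller cutoff), and always offers a
patient-permutation adjusted p (default 1,000 permutations) because
the nominal scan minimum is anti-conservative — the acceptance suite
measures both the calibrated permutation rejection rate and the
inflated nominal rate on null cohorts. Event-time ties use Breslow
throughout, the simplest consistent choice.

## 7. The synthetic-data generator

`sim_config()` defaults encode the study conditions the package
targets: three cancer types with 4, 4 and 5 cohorts (13 in total), a
cross-cancer core of 18 genes guaranteed in at least three cohorts of
every cancer, 17 paralog families of 3–8 members, a signature
containing 47% of the planted DEGs, a planted-DEG fraction of 10%,
effect sizes $|log2FC| \sim U[1,3]$ with random sign, i.i.d. residual
noise of sd 0.5 on the log2 scale, baseline gene means
$\mathcal N(8, 2^2)$, constant per-probe offsets (sd 0.3) so
multi-probe collapse has a well-defined truth, 20v20 groups, and one
unbalanced 40v5 cohort per cancer. Survival cohorts use standard
normal expression, exponential event times with hazard
$h_0 e^{\beta^\top x}$ and independent exponential censoring tuned to
the target censoring fraction (exact under the null).

Two deliberate truth-contract choices: (i) core and family-carried
effects draw $|log2FC|$ from $[1.5, 3]$ rather than $[1, 3]$ — an
effect sitting exactly on the calling boundary is recovered in only
about half of replicate cohorts at these group sizes, so a "guaranteed
core" planted at the boundary would not define a recoverable ground
truth; cancer-specific genes keep the full $[1, 3]$ range so
sensitivity remains a meaningful metric near the threshold. (ii) the
per-cohort family carrier rotates so that no member carries the
family's effect in three or more cohorts of one cancer; otherwise
family members would stochastically enter the ≥3-cohort core and the
planted core would no longer identify the qualified-mode intersection
exactly. All generator output is bit-reproducible from `(cfg, seed)`.

What the generator does **not** emulate: batch effects, array spatial
artifacts, intensity-dependent variance trends, probe cross-
hybridization, correlated genes, RNA-seq counts, or informative
censoring. Passing tests therefore demonstrate correctness of the
algorithms and calibration under clean conditions, not robustness to
those real-data pathologies.

## 8. Problem sizes used by the tests

The test and acceptance runs use scaled study conditions chosen as
representative while keeping simulations compact: 5,000 genes × 50
replicates for null calibration, 2,000 genes × 20 seeds for power,
5,000 probes × 20 seeds for prior recovery, 20 seeds × 100 repeats of
40v5 equalization, the full 13-cohort collection for core/family
recovery, n = 500 × 10 seeds for Cox recovery, and 200 null cohorts
(n = 60, 99 permutations) for scan calibration.

## 9. Known limitations

Single two-group factor only (no paired or multi-factor designs, no
array weights); gene identity is by normalized symbol with no alias
resolution; the enrichment module does no GO-graph propagation;
quantile normalization and clustering are QC aids, not batch
correction; the best-cutoff scan's nominal p is reported for
comparability with common practice but should never be quoted without
the permutation-adjusted p alongside.
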