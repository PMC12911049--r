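---
title: "Methods: sex-biased expression analysis in tumor transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased expression analysis in tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbias)
```

## The problem

Bladder cancer shows a striking sex disparity: men are diagnosed far more
often, yet women often face a more aggressive clinical course. Part of that
disparity is thought to be molecular — genes and microRNAs whose expression
differs between male and female tumors in ways that do **not** simply carry
over from normal tissue. `sexbias` implements an integrative pipeline for
finding such *tumor-specific sex-biased* (TSSB) features and tracing their
regulatory and prognostic consequences:

1. sex-differential expression (male vs female) in tumor and in adjacent
   normal tissue, separately for mRNAs and miRNAs;
2. TSSB set construction from the tumor/normal overlap structure;
3. filtering of experimentally validated miRNA–mRNA interactions by
   sex-stratified negative correlation, and discordance classification;
4. sex-stratified survival prioritization (median split, Kaplan–Meier,
   log-rank, univariate Cox);
5. hypergeometric over-representation analysis against user-supplied gene
   sets;
6. per-cell-type sex-biased expression of a prioritized panel in single-cell
   data.

Every stage can be exercised on a bundled synthetic-cohort generator with
planted ground truth, so the whole pipeline is testable without any external
download.

## Differential expression model

Counts for feature $i$ in sample $j$ are modeled as negative binomial,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_i), \qquad
\log \mu_{ij} = \log s_j + x_j^\top \beta_i,$$

with $\mathrm{Var}(K) = \mu + \phi\,\mu^2$. Size factors $s_j$ are
median-of-ratios: the per-sample median, over features expressed in every
sample, of the count divided by the feature's geometric mean. The design
always contains an intercept and the sex indicator (reference female, so
positive coefficients are male-biased); clinical covariates (age, stage,
grade, integer-coded) can be added — the convention used here is covariates
for the tumor mRNA model and none for miRNA models. The sex coefficient is
tested with a Wald statistic, $\mathrm{log_2FC} = \hat\beta_{sex}/\ln 2$,
and features are called significant at adjusted $P < 0.05$ **and**
$|\mathrm{log_2FC}| > 0.58$ (both strict; 0.58 is a 1.5-fold change).
Multiplicity is handled by Benjamini–Hochberg step-up; features whose IRLS
fit fails are excluded from the BH family rather than assigned $p = 1$,
keeping the family honest.

### Dispersion and the p-value reference

$\phi_i$ is estimated per feature by method of moments — Pearson-residual
matching against a Poisson mean fit, corrected by $n/(n-p)$ and floored at
$10^{-8}$ — and by default shrunk toward a $\phi \sim a_0 + a_1/\bar\mu$
trend fitted across features (log-scale midpoint between feature and trend).
This is deliberately lighter than a full empirical-Bayes treatment, which
this package does not replicate.

A consequence of a plain plug-in dispersion is that referring
$\hat\beta/\widehat{SE}$ to the standard normal is slightly anticonservative
at moderate $n$ (the statistic behaves like a $t$). The package therefore
uses a Student $t$ reference with $n - p$ degrees of freedom by default
(`pvalue = "normal"` restores the asymptotic reference). On null synthetic
cohorts (100 seeds × 200 features, 50 vs 50 samples) the observed
fraction of $p < \alpha$ is 0.0486 at $\alpha = 0.05$ and 0.0079 at
$\alpha = 0.01$ — inside the pooled 95% binomial envelopes, which the
acceptance suite re-verifies at run time.

Two numerical caveats worth knowing: (i) doubling every raw count is *not*
an exact no-op — median-of-ratios factors are invariant to a global scaling,
so the refitted dispersion and weights shift slightly; the coefficient is
exactly invariant only in the Poisson limit (the suite tests this as an
approximate invariance); (ii) with fewer model parameters than samples the
IRLS is clipped at $|\eta| \le 30$ to avoid overflow on degenerate features.

## TSSB set construction

Let $T$ and $N$ be the significant feature sets in tumor and normal tissue.
Shared features ($T \cap N$) are split by agreement of the male-vs-female
fold-change sign into *concordant* (the sex bias merely carries over from
normal tissue — in real cohorts these are dominated by Y-chromosome genes)
and *reversed* (the tumor flips the normal-tissue bias, a tumor-intrinsic
signal). The TSSB set is

$$\mathrm{TSSB} = (T \setminus N)\; \cup\; \{\text{shared, reversed}\},$$

equivalently $|\mathrm{TSSB}| = |T| - |\text{shared concordant}|$. The rule
is identical for genes and miRNAs. On the reference cardinalities (507
tumor, 856 normal, 68 shared with 51 concordant / 17 reversed) it yields
456 — distinguishing it from the naive tumor-only rule (439). A shared
feature with a zero fold change cannot occur (significance requires
$|\mathrm{log_2FC}| > 0.58$); this is asserted defensively.

## miRNA–mRNA pair filtering

Candidate pairs are validated interactions (miRTarBase-style table) with
*direct experimental evidence only* — prediction-only rows are dropped —
restricted to TSSB miRNAs and TSSB genes. For each pair, Pearson $r$ and a
two-sided $p$ ($t$ reference, $n-2$ df) are computed separately within male
and within female tumor samples on variance-stabilized expression; a pair
is retained when $r < 0$ and $p < 0.05$ in at least one sex (`retained_in`
distinguishes `male_only`, `female_only`, `both`). Correlation p-values are
*not* multiplicity-adjusted by default — retention is a raw-$p$ screen — but
`adjust = TRUE` applies BH per sex as a sensitivity analysis.

The variance-stabilizing transform is the declared substitute
$\log_2(\text{count}/s_j + 1)$: the values feed a rank-free correlation
only, where a monotone log-scale stabilization suffices, and the transform
is pluggable. Retained pairs are classified by the signs of the two tumor
fold changes into four categories; pairs whose miRNA and target are biased
toward *opposite* sexes (`M_mirna_F_gene`, `F_mirna_M_gene`) are flagged
discordant — the signature of sex-specific post-transcriptional repression.
Correlations are computed per sex stratum only (no pooled-cohort variant),
and a zero-variance stratum yields an undefined $r$ there, with retention
decided by the other stratum.

## Survival prioritization

Within each sex stratum, expression of each feature is dichotomized at the
stratum median — values strictly above go to "high", ties go to "low" (a
convention; configurable) — then compared with a two-group log-rank test
and a univariate Cox model on the high-vs-low indicator. The Cox partial
likelihood uses Efron tie handling and is maximized by Newton–Raphson with
step halving; monotone likelihoods (complete separation of the event order)
are *flagged*, not penalized — Firth correction is intentionally out of
scope. A feature is *unfavored* in a stratum when significant with
$HR > 1$ and *favored* when significant with $HR < 1$; the cross-sex
summary partitions features into male-only / female-only / both / neither.
The log-rank $p$ defines significance for that partition by default
(`use = "cox"` switches to the Wald $p$); strata with fewer than 4 samples,
or features whose split is degenerate, are skipped with a warning.

## Enrichment

Over-representation of a query set against GMT gene sets is the upper-tail
hypergeometric probability $P(X \ge k)$ with universe $N$, term size $K$,
query size $n$, overlap $k$, BH-corrected across terms, reported at
$padj < 0.05$ with $k \ge 2$. The default universe is the set of features
surviving the low-expression filter — an explicit, reproducible choice in
place of an annotation-database background that cannot be shipped.

## Single-cell analysis

Cells are filtered by the standard thresholds — mitochondrial fraction
> 10%, total UMIs < 1000, detected features < 300 or > 6000 (all
configurable; mitochondrial genes are recognized by the `MT-` prefix since
no gene list is assumed). Filtering is idempotent. Expression is
log-normalized as $\ln(1 + 10^4\,c_{ij}/\sum_i c_{ij})$. Per cell type,
male and female cells are compared per panel gene with the Wilcoxon
rank-sum test (cell-level testing, matching common practice; a pseudobulk
mode would be the conservative alternative when samples are few — with 4
male and 2 female samples cell-level tests do risk pseudoreplication, which
is why the boundary-respecting and null-calibration properties are tested
explicitly). The fold change is computed on de-logged counts-per-10k means
with a pseudocount of 1, $\log_2\frac{\bar m + 1}{\bar f + 1}$, so it reads
on the count scale; BH is applied within each cell type across the panel.

## The synthetic world

The generator states one fixed world; its defaults are conditions, not
dials, and were chosen once:

| parameter | default | rationale |
|---|---|---|
| cohort | 293 M / 106 F tumor, 10 M / 9 F normal | the sample-size asymmetry of a real bladder-cancer series |
| features | 1000 genes, 200 miRNAs | desk-scale stand-ins for ~19k genes / ~800 miRNAs |
| `nb_dispersion` | 0.1 | a typical bulk RNA-seq overdispersion magnitude |
| `effect_log2fc` | 1.5 | a clearly detectable planted effect at cohort n |
| biased fractions | 5% tumor, 2% normal | sparse sex effects, mostly tumor-side |
| `repression_strength` | −1 (log2 slope) | strong canonical repression |
| chromosomes | 90% autosome / 7% X / 3% Y | mirrors the mostly-autosomal findings |
| hazard | 1/1000 per day, censor 1/2000 | median OS of roughly two years with ~60% events |
| `survival_beta` | 0.8 per SD | a large, recoverable prognostic effect |
| single cell | 4 M / 2 F samples, 250 cells each | the sc cohort shape, desk scale |

Counts are NB with mean depth × baseline × $2^{\pm\text{effect}/2}$ (log-normal
baselines and depths); planted repression shifts a target's log2 mean by
`repression_strength` × the standardized realized miRNA log abundance in
tumor samples; survival is exponential with the log hazard shifted by
`survival_beta` × standardized log expression *within the designated sex
stratum only*; single-cell counts are per-cell multinomials with planted
per-type sex shifts on a named panel, and a stated fraction of cells built
to violate exactly one QC threshold. One master seed drives independent
per-generator substreams, so adding a generator never perturbs another;
identical seeds give bit-identical matrices.

What the generator does **not** emulate: library-preparation batch
structure, correlated gene modules, GC/length biases, ambient RNA or
doublets, non-proportional hazards, or the real mean–dispersion relation of
any cohort (no public effect-size distributions exist to calibrate
against). A green test therefore establishes that the *machinery* is
correct and calibrated in a well-specified world — not that the package
reproduces any particular cohort's headline numbers, which depend on the
real data and on estimation machinery explicitly out of scope.

One interaction worth noting: because all features share per-sample depth
factors, features are weakly positively correlated on the log scale; with a
planted survival effect on one gene, *other* genes show a small induced
association. This is a feature of real data too, and the null-calibration
checks use a fully null hazard.

## Design choices on open points

- **Low-expression filter** defaults to count ≥ 10 in ≥ 20% of samples
  (thresholds were stated to exist but not given).
- **Significance for the survival partition** uses the log-rank $p$
  (the defining test for the reported partition was ambiguous); configurable.
- **Median-tie convention**: ties to "low"; **Cox ties**: Efron.
- **Stage/grade coding**: ordered integers.
- **miRNA shared-feature exclusion** coincides with the gene rule; the
  single shared miRNA is treated as sign-concordant.
- **Run configuration** is JSON (no YAML parser in the dependency budget).

## Known limitations

No empirical-Bayes dispersion moderation or outlier handling; no
independent filtering of the BH family; no Firth correction for separated
Cox fits; no pooled-sex correlation variant; enrichment ships no annotation
databases; single-cell integration, clustering and annotation are inputs,
not computations. All empirical claims above (calibration fractions,
recovery rates, oracle agreement) are recomputed by the test suite and the
acceptance script — this vignette states none that they do not.
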