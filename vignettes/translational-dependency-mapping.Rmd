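---
title: "Translational dependency mapping: models, alignment, and downstream inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translational dependency mapping: models, alignment, and downstream inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transdep)
```

# The problem

Genome-wide CRISPR knockout screens measure, for each gene in each cell
line, a *gene effect* (CERES-like) score: how much fitness the line loses
when the gene is cut. Negative scores mean stronger dependency, and a score
below −0.5 conventionally marks a dependent line. Patient tumors cannot be
screened this way, but their transcriptomes can be measured. `transdep`
implements the pipeline that bridges the two: learn per-gene predictive
models of essentiality from cell-line expression, align patient
transcriptomes into the cell-line expression space, transpose the models to
obtain a predicted dependency map over patients, and then run the analyses
that make such a map useful — selectivity ranking, synthetic-lethality
discovery, genetic-interaction scoring of validation screens, survival and
drug-response association, and tumor-versus-healthy tolerability.

Every stage is exercised on synthetic cohorts with planted, exported ground
truth, so the whole pipeline is testable offline.

# Per-gene essentiality models

For each eligible gene (at least five dependent lines with score < −0.5
*and* five nondependent lines; `eligible_genes()`), an elastic net with
mixing parameter α = 0.5 regresses the gene's essentiality profile on
genome-wide expression (`fit_gene_model()`). The penalty λ is chosen at the
minimum of the 10-fold cross-validated squared error over a 100-point path,
log-spaced four decades down from the smallest λ that zeroes every
coefficient (computed with the same 1/n-variance standardization glmnet
uses internally, so the path's first point is exactly null). Performance is
the Pearson correlation R between the *pooled out-of-fold* predictions and
the observed scores; pooling rather than per-fold averaging is used because
at n ≈ 100 lines the per-fold estimates are noisy. The two-sided P for R
uses the usual t approximation with n − 2 degrees of freedom, and
Benjamini–Hochberg FDR is computed across all attempted genes. A model
passes when R > 0.2 and q < 10⁻³.

Coefficients are reported on the original feature scale (so
`intercept + Σ coef · expression` is the prediction that `predict_map()`
computes); the self-inclusion rank of the target gene among its own
features is ranked on standardized-coefficient magnitude so that it is
scale-free. The target gene's own expression is deliberately *not*
excluded from the feature set — self-predicting models are biologically
meaningful (expression-driven dependencies) and common.

Three model variants share this machinery: expression-only (the default,
and the one transposed to patients, since patient cohorts always have
expression but often lack the genomic features), multi-omics (expression +
binary mutation + copy number, concatenated after per-feature
standardization inside glmnet), and a confounder null (lineage one-hot plus
simulated nuisance covariates) whose cross-validated R distribution
provides a floor that real models must clear. A logistic elastic net
(`fit_mutation_classifier()`) predicts per-gene mutation status from the
same expression features; comparing its cross-validated AUC with the
essentiality model's AUC (sensitive class: observed score < −0.5) shows
whether dependency signal is merely mutation-status signal read through
expression.

# Transcriptional alignment

Biopsies are mixtures: a fraction (the *purity*) of the signal is
malignant, the rest stromal and immune. Admixture is additive in linear
expression space, so the pipeline treats it there. Alignment of a target
cohort onto the cell-line cohort proceeds in three steps
(`align_cohorts()`):

1. **Quantile normalization** of both cohorts to the pooled per-rank mean
   reference (`quantile_normalize()`), which removes library and platform
   distributional differences while preserving within-sample ranks.
2. **Contrastive PCA** (`contrastive_pca()`): eigendecomposition of
   `C_target − α_c · C_cells`, the difference of gene–gene covariance
   matrices. Directions that carry variance in tumors but not in cell
   lines are, by construction, dominated by stromal admixture. The top
   components (4 for tumor cohorts, 3 for PDX — xenografts carry less
   stroma — 0 for healthy tissue) are removed from *both* cohorts by
   orthogonal projection (`remove_components()`), since both must live in
   the same reduced space for the models to transfer. The contrast weight
   α_c defaults to 1 and is configurable.
3. **Cluster-matched shift correction** (`cluster_match_correct()`): joint
   k-means over the pooled samples, then each cluster's tumor members are
   shifted by the difference between the cluster's tumor centroid and the
   nearest cell-cluster centroid. This removes residual cohort-level
   offsets lineage by lineage rather than globally.

Healthy-tissue cohorts have no malignant/stromal dichotomy, so a
quantile + per-gene location-scale correction toward the cell cohort's
means and SDs is used instead (`gtex_style_correct()`), with the per-gene
adjustment shrunk toward the global adjustment by weight n/(n + n₀)
(default n₀ = 10) to stabilize small cohorts. This is a deliberate
location-scale stand-in for empirical-Bayes batch correction, documented
as such.

The diagnostic that motivates all of this is `purity_diagnostic()`: the R²
between each model's predicted scores and tumor purity, before and after
alignment. Models trained on pure cell cultures have no business reading
stromal content; a drop in the median purity R² (Wilcoxon tested) is the
pipeline-level criterion of alignment success.

A geometric subtlety worth recording: quantile normalization re-centers
every sample column, so the contrastive loading removed by the full
pipeline aligns with the *across-gene-centered* version of the planted
stromal indicator, not the raw indicator. The planted-direction test is
therefore stated on the contrast of the raw cohorts, where the indicator
itself is the right reference; pipeline-level quality is asserted through
the purity diagnostic.

# Transposition and rescaling

`predict_map()` evaluates each passing model linearly on the aligned
target expression. Models with features missing from the target are
skipped, never zero-filled — zero-filling silently drags predictions
toward the intercept. `rescale_map()` then regresses *measured* scores on
the models' *cell-cohort predictions* per gene and applies the fitted
affine map to the target predictions, putting them on the measured-score
scale. The map is monotone affine, so per-gene correlations and sample
rankings are provably unchanged; the least-squares identities (slope 1 /
intercept 0 at predicted ≡ measured; matched means after rescaling) are
asserted exactly in the tests.

Cohort structure is summarized by Ward.D2 hierarchical clustering over
samples (`lineage_cluster()`, with the adjusted Rand index against known
lineages) and by `gof_association()`: a two-sided Wilcoxon rank-sum test
per gene of predicted scores in carriers of a gain-of-function event
versus non-carriers, with a direction flag when carriers are more
dependent.

# Selective dependencies (NormLRT)

A gene whose scores are normal across the cohort is uniformly essential or
uniformly dispensable; a strongly selective dependency has a heavy,
usually left, tail. `normlrt()` scores this as
`2·(loglik_skewt − loglik_normal)`, with the normal fit closed-form and
the skew-t fit by numerical maximum likelihood. The skew-t density used is
the Azzalini form

$$f(x) = \frac{2}{\omega}\, t_\nu(z)\, T_{\nu+1}\!\Big(\alpha z
\sqrt{\tfrac{\nu+1}{\nu+z^2}}\Big), \qquad z = \frac{x-\xi}{\omega},$$

with location ξ, scale ω, slant α and degrees of freedom ν kept in
[2.1, 100] through a logistic transform — the lower bound keeps the
variance finite, the upper bound is operationally "normal-like". Three
optimizer starts (symmetric-t, left-skew, right-skew) guard against local
optima; the statistic is clamped at zero because the normal sits on the
boundary of the family and small negative values are optimizer noise. The
statistic is used for ranking only; no boundary-corrected P value is
attached.

Because the log-likelihood ratio grows roughly linearly with sample count,
statistics from cohorts of different sizes are not comparable.
`bootstrap_scaling()` resamples the measured cohort up to the target size,
recomputes the statistic, and fits a slope through the origin (a statistic
of zero must map to zero); the slope rescales the larger cohort's
statistics onto the source scale. Rescaling is a positive scalar and never
changes the within-cohort ranking.

# Synthetic-lethality discovery

`lasso_sl()` regresses each gene's dependency profile on all binary LOF
(damaging mutation or deletion) event columns with a lasso (λ at the
5-fold CV minimum), keeping coefficients more negative than −0.3 —
carriers at least 0.3 score units more dependent after shrinkage, on the
original 0/1 predictor scale. The original scale is used deliberately: a
planted effect of −0.6 at 20% prevalence has magnitude ≈ 0.24 on the
standardized-predictor scale and would be invisible to a 0.3 threshold
there, while glmnet's default reporting (which the threshold convention
comes from) is the original scale. Kept coefficients are confirmed by a
two-sided Welch t-test (the unequal-variance form, since carrier groups
are small and variance equality is not defensible) with BH correction
across every tested pair; LOF genes outside the 3–70% prevalence band are
excluded before fitting.

The mutual-exclusivity stage asks whether the candidate partner belongs to
a set of LOF events that are mutually exclusive across patients and
concentrated in the most dependent ones. Two functions implement this:

* `mutual_exclusivity()` — the unanchored greedy search over a weighted
  coverage objective: with per-sample weights w ≥ 0 and coverage count
  c\_s over the chosen set, each covered sample contributes
  `w_s · (2 − c_s)` (+w once-covered, 0 twice, −w for each further hit).
  The greedy is multi-start (restarted from each of the best single genes,
  which makes it exact for pairs), and its permutation P re-runs the full
  greedy on weight-permuted data. This operation is validated against a
  brute-force subset enumeration.
* `me_anchor_test()` — the candidate-anchored test used by the funnel.
  The partner's exclusivity set is first built from the LOF matrix
  *alone*: genes whose carrier overlap with the anchor (and pairwise with
  every chosen member) is depleted below chance by a one-sided
  hypergeometric test. Only then is that frozen set's weighted coverage
  objective permutation-tested against the dependency weights. Because
  set selection never sees the weights, the permutation null is valid;
  because the set is not re-optimized per permutation, the test is not
  diluted by selection noise. The unanchored rerun-the-greedy P is
  calibrated but, at cohort sizes in the hundreds, its
  selection-maximized null swallows effects of the size studied here;
  the anchored test is the powered alternative and the one `sl_funnel()`
  applies at P < 0.01.

Weights in both are the depth below the cohort's 25% dependency quantile
(`max(0, q₂₅ − score)`) rather than the raw negated score: only the
dependent tail should carry weight, otherwise nearly every sample has
positive weight and coverage mass swamps association.

`paralog_filter()` keeps candidates that are annotated paralogs *or* have
phylogenetic distance strictly below 1.5 (OR semantics; an annotated
paralog with missing distance survives). `sl_funnel()` chains the stages
and logs the per-stage survivor counts, which are non-increasing by
construction.

# Dual-knockout screen analysis

Validation screens use constructs of four guides (two per gene;
non-targeting fillers), counted from reads by exact match of the sequence
between fixed flanks (`count_guides()`; anything imperfect is unmapped).
Libraries are TMM-normalized (edgeR's implementation behind
`tmm_factors()`; trim 30% by M, 5% by A, factors normalized to geometric
mean 1). `screen_l2fc()` computes per-replicate log2 fold changes of
day-14 counts against the plasmid library on a common effective library
size with a 0.5 pseudo-count, summarizing replicates by mean and
one-sample t — a deliberate simplification of a moderated linear model,
defensible at three replicates and documented here.

`gi_scores()` z-scores all construct L2FCs against the NT×NT null
distribution (at least 10 such constructs required), collapses multiple
constructs per target to the median, and scores each dual-knockout pair as
`observed z − (z_A + z_B)`; the differences are z-scored across all pairs
(`diff_z`) and called synthetic lethal below −2 or buffering above +2. The
±2 call bar is a package choice — the underlying convention is "observed
significantly below expected" without a stated numeric threshold.
`screen_concordance()` correlates `diff_z` between runs over shared pairs.

# Clinical outcome association

`maxstat_cutpoint()` dichotomizes a dependency score against survival by
the maximally selected rank statistic: log-rank (Savage) scores are
computed once, every admissible cutpoint (both groups within the 10–90%
quantile range) is scanned by cumulative sums, and the selection is
corrected by permuting the score–outcome pairing and recording the
permutation distribution of the *maximum* statistic. Permutation rather
than the asymptotic maximally-selected-statistic approximation keeps the
test exact at these cohort sizes with no tabulated constants; both the
corrected and the naive P are reported, and the corrected one feeds the
BH step. `cox_hr()` wraps a proportional-hazards fit (Efron ties,
optional strata); non-convergence and separation are flagged rather than
reported as a number. `pfi_scan()` chains maxstat → log-rank → Cox per
gene with lineage strata, an exclusion list, a 30-sample stratum floor,
and BH at FDR < 0.2, reporting hazard ratios oriented so HR > 1 means
stronger dependency predicts worse outcome. `sl_survival()` compares
carriers (partner LOF *and* predicted dependency in the lowest quartile —
the 25% carrier-group quantile is a package decision, echoed verbatim in
the output) against everyone else.

`response_assoc()` handles treatment response: Wilcoxon plus ROC-AUC for
binary response (sensitive class at negative scores), Pearson correlation
for continuous burden change, refusing cohorts under 20 samples.
`dep100_subtype()` selects the top-variance dependency signature (variance
rather than MAD — the convention is unstated in the field source, variance
chosen and documented), clusters with Ward.D2, and scores subtype recovery
by leave-one-out LDA with per-class one-vs-rest AUC. `driver_enrichment()`
takes the lowest-decile patients by a gene's score and Fisher-exact-tests
(one-sided, enrichment) every sufficiently prevalent variant, BH within
variant class (prevalence floors: 5% mutations, 10% deletions and
amplifications).

# Tolerability

`window_scan()` contrasts predicted dependency between tumors and matched
healthy tissue per gene and pairing with a Welch t statistic, negative
meaning stronger dependency in tumor (a therapeutic window). Both maps
must carry provenance `predicted+rescaled` from the same model set —
comparing maps on different scales is refused, reflecting the requirement
that the predicted score scales be comparable before any cross-cohort
subtraction. Swapping the roles flips every t exactly (asserted in
tests). `toxicity_profile()` summarizes mean essentiality of annotated
toxicity target sets per healthy tissue against the complement set.

# The synthetic cohorts

`make_cell_cohort()` draws log2 expression as
Normal(gene mean + lineage shift, 1) with gene means ~ N(7, 1.5²) and
lineage shifts ~ N(0, 1); 20 of 500 genes carry a planted sparse linear
essentiality model (5 features, coefficients ±U(0.15, 0.3), residual SD
0.2), chosen so per-gene score spreads land in the 0.5–0.9 band typical of
gene-effect scores. Remaining genes are pure noise around −0.5 (SD 0.5),
except an inert fifth near +0.2 that the eligibility filter must drop.
Binary mutations (prevalence 5–30%) and CNV complete the multi-omics
inputs.

`make_tumor_cohort()` reuses the same generative models: malignant
expression is drawn from the cell-line process, stromal profiles shift a
15% gene subset by +4 log2 units, and the biopsy signal is
`purity·malignant + (1−purity)·stromal` mixed *in linear space* and
re-logged, with purity ~ Beta(5, 2) — this is exactly the structure
contrastive PCA is designed to remove, and the linear-mixing choice is a
modeling convention of this package. Each planted synthetic-lethal partner
(default 5 pairs at Δ = −0.6) is embedded in a 3-gene LOF module with
mutually exclusive carriers (per-member prevalence 8–15%), all of whose
members sensitize the paired gene — the redundancy structure the
exclusivity filter presumes. Survival times are exponential with
log-hazard linear in the hazard gene's centered latent essentiality,
administratively censored at 36 time units (≈30–50% events). A window gene
gets an all-tumor dependency shift of −0.5 relative to healthy tissue.
`make_healthy_cohort()` produces tissue-structured expression with an
affine batch distortion and no admixture. The default cohort sizes are 100
cell lines, 300 tumors (500 where the synthetic-lethality stages are
powered), and 120 healthy samples.

The tumors' *latent* essentiality (planted models evaluated on the
malignant component, plus SL/window shifts) is exported in the truth
object, and the SL, survival and tolerability stages are exercised on it:
an expression-predicted map cannot carry a planted LOF effect that
bypasses expression, so the latent map is the right substrate for testing
those stages, while the transposition stages are tested on the predicted
maps against this same latent truth.

One global seed drives stream-split per-generator seeds, so any cohort can
be regenerated independently and bit-identically.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: measurement platform idiosyncrasies
(microarray vs RNA-seq), nonlinear expression–essentiality relationships,
copy-number-driven screen artifacts, correlated LOF co-occurrence beyond
the planted modules, informative censoring, and cohort sizes at consortium
scale. Conclusions about those require the real inputs.

# Numerical choices and degenerate inputs

Constant essentiality profiles fail model fitting with an explicit flag;
constant predictions are left unscaled and flagged in rescaling; constant
purity makes the diagnostic refuse; zero-variance genes skip the scale
step of the healthy-cohort correction with a log entry; groups under
their floors (3 for GOF tests, 10 for SL survival carriers, 5 per
class/side elsewhere) are skipped and logged, never silently imputed.
Permutation P values carry the +1 correction and can never be zero. Gene
set mismatches between cohorts are resolved by intersection, never
imputation. All writers emit deterministic byte streams.

Problem sizes throughout the test-suite and the acceptance script (cohorts
of 100 lines / 300–500 tumors, 100-simulation calibrations, 10–20 seed
replications) are the package's choice of desk-scale study conditions;
they are stated here once so results are interpreted at that scale.

# Known limitations

The location-scale healthy-tissue correction is not an empirical-Bayes
batch correction; the anchored exclusivity test conditions on a
LOF-derived set rather than re-running a full search; replicate
aggregation in screens is unmoderated; no closed-form significance is
offered for NormLRT; and the pipeline makes no attempt at genome-scale
performance tuning — matrices are dense and cohorts are assumed to fit in
memory.
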