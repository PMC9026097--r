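---
title: "modscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{modscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

modscape implements the statistical core of a comparative transcriptomic
analysis of fumarate esters in astrocytes: four treatment groups (a vehicle
control, CTL, plus monomethyl fumarate, MMF; dimethyl fumarate delivered as a
prodrug, DRF; and an isosorbide ester, IDMF), three replicates each, profiled
on expression microarrays, with a larger independent astrocyte data set used to
define co-expression modules. All inputs are normalized log2 intensity
matrices; probe-level normalization is out of scope. This vignette records the
models, the numerical choices, and what the synthetic-data generator does and
does not emulate.

## Differential expression

Each treatment is compared with the control by a per-gene two-sample linear
model on log2 intensities. With group sizes $n_a$, $n_b$ the estimate is the
difference of group means, $\hat\beta_g = \bar{x}_{ga} - \bar{x}_{gb}$ (the
log2 fold change), with pooled residual variance $s^2_g$ on
$d = n_a + n_b - 2$ degrees of freedom. Because $d = 4$ here, the per-gene
variance is noisy; it is shrunk toward a prior by the standard empirical-Bayes
construction: assume $s^2_g \sim s_0^2 \chi^2_d / d$ given the true variance
and a scaled inverse-chi-square prior with hyperparameters $(d_0, s_0^2)$.
These are estimated by moment matching on the log scale: with
$z_g = \log s^2_g$ and $e_g = z_g - \psi(d/2) + \log(d/2)$, the excess of
$\mathrm{var}(e)$ over $\psi'(d/2)$ determines $d_0$ through a trigamma
inversion (Newton's method, tolerance $10^{-8}$, values above $10^6$ treated
as infinite), and $s_0^2$ follows from the mean. The posterior variance
$\tilde s^2_g = (d_0 s_0^2 + d s^2_g)/(d_0 + d)$ yields the moderated
statistic $t_g = \hat\beta_g / (\tilde s_g \sqrt{1/n_a + 1/n_b})$ with
$d + d_0$ degrees of freedom (normal when $d_0 = \infty$). Two limits anchor
the implementation and its tests: $d_0 = 0$ reproduces the ordinary
equal-variance t-test, and $d_0 = \infty$ uses the common prior variance for
every gene. The test suite also cross-checks the fit against the limma
implementation of the same model on a shared fixture.

"Generalized least squares" in this two-group balanced design reduces to
ordinary least squares per gene; no correlation structure is modeled.

DEG calling uses two printed threshold sets, applied with strict inequalities
on both scales: lenient, raw $p < 0.05$ with linear fold change $> 1.25$ or
$< 0.80$; stringent, BH-adjusted $p < 0.10$ with the same fold-change gates.
A gene at exactly $FC = 1.25$ is not a DEG. Fold-change gates operate on the
anti-logged model coefficient, which for this design equals the ratio of group
geometric means. BH adjustment is delegated to `stats::p.adjust`; a
hand-computed step-up oracle pins its behavior in the tests.

## Filtering

Three per-comparison gene filters precede testing, mirroring standard
microarray practice:

* **Detection.** A gene is detectable on an array when its intensity is
  strictly above that array's own 20th percentile (type-7 quantile, computed
  over all genes on the array after probe collapse); a gene enters a
  comparison when detectable in at least 2 of its 6 samples. "Above"
  is read literally as strict: on a degenerate array where all genes are
  equal, nothing is detectable.
* **Variability.** Genes whose SD across all samples (n−1 denominator) falls
  below the 5th percentile of all gene SDs are dropped; ties at the floor are
  kept ("below" excluded, so `>=` retains).
* **Single-sample outliers.** When one sample is designated as a borderline
  outlier, a gene is excluded only when that sample's |z| (against the gene's
  own across-sample mean and SD) exceeds 2.50 *and* its value is the strict
  minimum or maximum. Both conditions are required; a tied extremum is kept.
  With no designated sample the filter is a warning no-op.

Probe-to-gene collapse keeps, per gene, the probe with the highest mean across
all samples, breaking exact ties by lexicographic probe ID and logging them.
Sample-level screening offers hierarchical clustering (Euclidean, average
linkage) and a PCA screen: genes are standardized, samples are projected, and
the most extreme PC1 score is tested with the two-sided maximum normalized
residual (Grubbs) test using the closed-form t-based p-value, which the test
suite calibrates against a 100,000-draw Monte-Carlo null.

## Co-expression modules

Modules are learned on an independent reference matrix (24 samples by
default). Each gene is centered and scaled to mean 0, SD 1 across the
reference samples (per-gene scaling; the alternative per-array reading of the
source description is noted and not used, since clustering distances require
comparable gene profiles). Genes are clustered with Euclidean distance and
average linkage, and the dendrogram is pruned by a variable-height rule: a
branch is accepted as a module when it has at least `min_module_size` leaves
(default 25) and its internal merge height sits at least `prune_depth`
(default 0.15) below its *attachment height* — the height at which its lineage
last joined a sibling with at least `min_module_size` leaves. Ignoring
insubstantial siblings makes the rule robust to straggler genes that chain
onto a tight branch near the treetop, which otherwise mask the height gap. The
coarsest qualifying branch wins; everything else is module 0 (unassigned).
Under the factor model used in the generator the expected relative gap of a
true module is $1 - \sqrt{1 - \bar r}$ (about 0.45 at within-module
correlation 0.7), while pure-noise branches complete within a few percent of
their attachment height, so 0.15 separates the two regimes with a wide margin;
it is a geometry-derived default, not a fitted constant.

Modules are labeled `<gene>-<size>` by the member gene with the most
annotation terms (ties lexicographic, label collisions suffixed), represented
by their medoid (the member minimizing summed Euclidean distance to the other
members), and connected in a network where medoid profiles have signed
Spearman correlation at or above 0.80 — signed, not absolute, and inclusive at
the boundary, with a $10^{-9}$ numerical tolerance so exact-boundary rank
correlations keep their edge. Differential module expression (DEM) is a
two-sided Wilcoxon rank-sum test of member log2 fold changes against all other
detectable genes, BH-adjusted across modules, significant at FDR < 0.05; the
implementation ranks the universe once and uses the tie- and
continuity-corrected normal approximation, switching to the exact distribution
for modules with at most 10 detectable members.

## Signature and gene-set statistics

Directional concordance between a compound's fold changes and a signature
(e.g. the up-regulated half of a transcription-factor activation signature)
is tested two ways, both reported: a two-sided Fisher's exact test on the
2×2 table {signature, background} × {increased, decreased} over detectable
genes, and an exact binomial test of the signature's up-fraction against 50%.
Genes with log2 fold change exactly 0 are excluded from the fractions and
counted separately. The cumulative-overlap **area statistic** ranks all
detectable genes by log2 fold change (descending, ties by gene ID) and
averages $C(k) = (\text{members among top } k)/M - k/N$ over $k$; it lies in
$[-0.5, 0.5]$, is positive when the signature concentrates among increased
genes, flips sign exactly under rank reversal, and is paired with a two-sided
rank-sum p-value on member ranks.

Annotation enrichment is a one-sided upper-tail hypergeometric test per term
with BH adjustment (the conditional, ontology-aware variant is out of scope).
Disease-gene tables aggregate membership across sources into tiers (number of
sources linking a gene), with tier filters exposed. Two resampling nulls use
the add-one empirical estimator $(1 + \#\{\text{null at least as extreme}\}) /
(\text{trials} + 1)$, so p-values are always in $(0, 1]$ and exactly
replayable from their seed: the mean |log2FC| of a gene set against 10,000
equal-sized random sets, and the mean nearest-locus distance of a top-gene
list against 1,000 random draws (lower tail — closeness is the hypothesis —
with a two-sided variant behind a flag, and p < 0.10 flagged as marginal).

Cross-study comparisons reuse the same machinery: correlation of fold-change
vectors (Pearson or Spearman) with sign-quadrant fractions, and one-sided
hypergeometric overlap of top-k lists (k = 100 by default) taken by signed
fold change over the shared detectable universe.

## GWAS proximity

Gene bodies are intervals, loci are points (both 0-based, half-open on input).
The distance is the gap in bases between the locus and the gene body: 0 when
the locus falls inside or immediately adjacent, and the count of strictly
intervening bases otherwise (the GenomicRanges convention; computation goes
through `distanceToNearest` and is pinned to a brute-force all-pairs oracle in
the tests). Genes with no same-chromosome locus get infinite distance; they
are excluded from mean-distance statistics and counted, rather than silently
dropped, to avoid bias on sparse fixtures. The window-overlap scan reports,
per distance window, a one-sided Fisher test of top-gene membership in the
near set plus the background near-fraction curve; counts are monotone in the
window by construction.

## Promoter motifs

Promoters are 5,000 bp upstream sequences, one per gene. PWMs are per-position
probability models over A/C/G/T with a pseudocount (default 0.01) and a
background (default uniform); scanning scores every window on both strands
with log2 odds, N contributing 0, and calls hits at 80% of the maximal
achievable score by default. Reverse-strand hits are reported at the window's
forward-strand start. Enrichment among DEGs uses a logistic model per PWM,

$$\mathrm{logit}\, P(\text{DEG}) = \beta \cdot \text{motif} + s(\text{GC})
  [+ s(\text{length})],$$

where the motif feature is the hit count (maximal score behind a flag) and
$s(\cdot)$ is an unpenalized cubic B-spline with interior knots at covariate
quintiles — a fixed-basis stand-in for a semiparametric smooth that keeps the
fit a plain IRLS/`glm` problem with an exact 1-df likelihood-ratio test for
$\beta = 0$, BH-adjusted across PWMs. Quasi-separation (non-convergence or
|β| > 15) triggers a ridge-penalized refit (λ = 10⁻⁴) and a flag. A constant
motif feature is an error naming the PWM. The IRF-family profile runs the same
model per PWM per DEG set and histograms hit positions in 250-bp bins for PWMs
passing FDR < 0.05; positions are reported within the promoter window only.

## Small-sample validation statistics

`exact_wilcoxon` enumerates all $\binom{n_x+n_y}{n_x}$ rank assignments for
tie-free samples with $n_x + n_y \le 12$ and reports the two-sided
$p = 2\min(\text{lower tail}, \text{upper tail})$, capped at 1 — the
convention under which the 3-vs-6 reporter-assay configuration with the
smaller group at ranks {1, 2, 4} gives $p = 4/84 \approx 0.048$. Larger or
tied samples use a moment-corrected normal approximation: the exact first four
moments of the rank sum under sampling without replacement from the midrank
population feed an Edgeworth expansion (skewness and kurtosis terms) with
continuity correction. The correction matters: the plain continuity-corrected
normal errs by up to 0.035 against exact enumeration at 2-vs-10, while the
Edgeworth form stays within 0.016 across every tie-free configuration at
$n_x + n_y = 12$ (checked exhaustively in the tests).

ΔΔCt fold changes are $2^{-\Delta\Delta C_t}$ with the target Ct normalized by
a reference gene per sample and by the calibrator group's mean ΔCt, so the
calibrator group has mean relative expression 1 on the ΔCt scale by
construction. Fisher's LSD uses the one-way ANOVA pooled MSE and residual df
for all pairwise t-tests, unprotected (no omnibus F gate), and assigns compact
letters as the maximal cliques of the non-significance graph with groups
ordered by descending mean — so two groups share a letter exactly when their
pairwise p is at or above α.

## The synthetic-data generator

Every statistic above is exercisable without downloads via generators that
plant known structure:

* **Experiment**: gene baselines N(7, 1.5²) on the log2 scale, i.i.d. Gaussian
  noise (SD 0.25 by default, a typical residual scale for normalized arrays),
  and per-group mean shifts of ±1 log2 unit in planted gene sets. Default
  planted fractions (MMF 3.1%, DRF 2.6%, IDMF 10.9%) mirror the relative
  breadth of the three compounds' effects, with a 2:1 up:down split for MMF
  and balanced splits otherwise.
* **Reference**: module genes load on per-module latent factors,
  $x = \lambda f + \sigma\varepsilon$, giving expected within-module
  correlation $\lambda^2/(\lambda^2 + \sigma^2)$; module sizes are drawn
  within a configurable range (25–196 by default). Non-module genes are pure
  noise.
* **Genome**: non-overlapping gene intervals on synthetic chromosomes with
  loci either planted within 100 kb of designated genes or placed uniformly.
* **Promoters**: i.i.d. backgrounds with configurable GC content, with exact
  PWM consensus instances inserted at recorded positions.

Each generator draws from a private RNG stream seeded explicitly and restores
the caller's RNG state, so identical parameters give byte-identical output and
the resampling stages are exactly replayable. The generators intentionally do
*not* emulate probe-level physics, array batch structure, correlated noise,
mean–variance trends, or realistic sequence composition; passing tests
demonstrate that the statistics recover known structure under their own model
assumptions, not that those assumptions hold for any particular real data set.

## Problem sizes and numerical conventions

The test and acceptance workloads use 5,000-gene universes for DE calibration
and recovery, 2,000 genes × 24 samples for module recovery, 200-repetition
uniformity checks for the resampling nulls at 1,000 trials each, and 10,000
trials for the single |FC|-null run — sizes at which the checked quantities
(KS uniformity, recall, adjusted Rand index) are stable across seeds while a
full suite completes in a few minutes on one CPU. Quantiles are type-7
everywhere. Empirical p-values use the add-one estimator. Percentile and
fold-change gates are strict; SD floors and network thresholds are inclusive.
All writers emit a header comment with the package version and generating
seed; readers skip `#` lines and report format errors with line numbers.

## Known limitations

Single-factor, two-group contrasts only; no duplicate-correlation or
multi-factor designs. The hypergeometric enrichment ignores annotation-graph
structure. The module step does not build weighted (soft-threshold)
correlation networks or eigengenes — medoids stand in for module profiles. The
GWAS step does no LD-aware locus-to-gene mapping. The motif model adjusts for
GC and length only, and the 80%-of-max hit threshold, while conventional, is
arbitrary; both the threshold and the count-vs-score feature choice are
exposed as parameters.
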