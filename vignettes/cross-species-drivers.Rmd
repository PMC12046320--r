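---
title: "Cross-species driver discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species driver discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carsx)
```

`carsx` chains six analysis stages — synthetic cohort generation, moderated
differential expression, cross-species integration, mutual-information
regulon inference, activity-based hidden-driver filtering, and gene-set
enrichment — into one reproducible driver-discovery pipeline. This vignette
explains the statistical model behind each stage, the tunable parameters and
their defaults, and the design choices that were genuinely open.

## Moderated differential expression

Expression enters on the log2-CPM scale
(`log2(count / libsize × 1e6 + pseudocount)`; pseudocount 1 by default, a
common convention that keeps zeros finite). For a two-group comparison the
statistic is the empirical-Bayes moderated *t*: per gene, the pooled
residual variance $s_g^2$ on $d_g$ degrees of freedom is shrunk toward a
prior $(d_0, s_0^2)$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad t_g = \frac{\overline{x}_{case} - \overline{x}_{ctrl}}
{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

referred to a $t$ distribution on $d_0 + d_g$ df. The hyperparameters are
estimated by method of moments on $\log s_g^2$ (matching the theoretical
log-F mean and variance; the unit tests verify exact agreement with
`limma::eBayes` on random data). `d0` is exposed as an override: `d0 = 0`
reduces to the ordinary pooled *t* (the oracle used in tests), `d0 = Inf`
to a single common variance. Signed Z-scores are
$z = \mathrm{sign}(\mathrm{log2FC}) \cdot \Phi^{-1}(1 - p/2)$ with $|z|$
capped at 8.21 — the practical limit of the double-precision normal
quantile — so downstream Stouffer combinations stay finite. Genes constant
across all samples are reported with $p = 1$, $z = 0$ and flagged. No
expression pre-filter is applied by default; `min_mean` exposes one, since
reasonable analyses differ here.

## Cross-species integration

Orthologs are merged by case-insensitive symbol identity (1:1 only;
symbols that collide after uppercasing are ambiguous and dropped with a
message), or by an explicit two-column map. Anchor selection follows three
steps: per-species signatures at $|z| > 1.96$; restriction to genes whose
fold-change sign agrees between species; size equalization of the two
lists to the smaller one, ranked by $|\mathrm{log2FC}|$ within species.
Ties at the cutoff rank go to the lexicographically smaller symbol, and
all set operations are order-invariant, so the selection is fully
deterministic. Both the per-species signatures and the sign-consistent
shared set are retained on the result, because the two are distinct
objects: the former describe each species' response, the latter is the
cross-species signature whose overlap significance is assessed by a
two-tailed Fisher exact test. The test universe is the merged gene count —
only genes surviving the ortholog merge are eligible for either set.

The response score is PC1 of a PCA over the anchor genes after z-scaling
each gene *within* its species (which is also the only batch handling
applied — species location and scale are removed, nothing more). PC1's
sign is arbitrary in principle; it is fixed so that the anchor with the
largest absolute loading gets a positive loading, a convention chosen
purely for determinism. The score is evaluated by ROC/AUC
(Mann–Whitney form, ties counted 0.5) with a stratified bootstrap
percentile CI (2,000 replicates by default); accuracy at the
Youden-optimal threshold is reported alongside, since a single published
"accuracy" number can refer to either quantity. The combined gene ranking
is the Stouffer statistic $(z_h + z_m)/\sqrt 2$, ranked descending with a
lexicographic tie-break; it is based on differential *expression*
Z-scores by default (an activity-based ranking can be fed through the same
function, as both are `de_table`s).

## Regulon inference and activity

The network layer is a desk-scale ARACNe-family procedure centred on a
candidate driver list supplied by the caller (the package deliberately
ships no TF/signaling annotation). Mutual information uses equal-frequency
(quantile) binning with $n_{bins} = \max(2, \lfloor\sqrt n/2\rfloor)$ and
the plug-in estimator in nats — simple, testable, and exactly
$\log n_{bins}$ on self-pairs when $n$ is a multiple of the bin count,
which gives the tests a closed-form anchor. Rank-based binning makes the
estimator invariant under monotone transforms; ties are broken by
position.

Each of the `n_bootstraps = 100` iterations resamples samples with
replacement, screens driver–gene pairs against a permutation null, and
applies the data-processing inequality: in every fully connected triangle
the weakest edge is dropped when it is weaker than both others minus
`dpi_tolerance` (default 0, the classic strict setting). Two numerical
choices matter here and were settled after observing failure modes of the
naive alternatives:

* the permutation null must preserve the duplicate-column coupling that
  resampling induces — the driver row is permuted in the *original*
  sample space and then passed through the same bootstrap indices;
  permuting the resampled row destroys that coupling and yields a null
  far below the bootstrap MI of genuinely independent genes;
* the screen is held at family-wise level `alpha = 0.05` across the
  candidate pairs (a moment-matched gamma extrapolation of the 100-draw
  permutation null — the plug-in MI null is approximately a scaled
  chi-square). A per-pair 5% level persistently admits the upper tail of
  chance dependencies of the realized data: those pairs pass a stable
  fraction of bootstraps, so no support-count consensus can remove them,
  and regulon precision collapses to ~0.5.

The consensus step keeps edges whose bootstrap support beats a binomial
tail test at `consensus_p = 0.01` (null support rate `alpha / n_pairs`,
Bonferroni-corrected across candidate edges). Edge weight is the mean MI
over supporting bootstraps; the edge sign is the sign of the Spearman
correlation on the full data, preferred over per-bootstrap signs for
stability. With one bootstrap and the consensus disabled the procedure
reduces to a deterministic single-pass MI threshold + DPI, which the test
suite checks against an exhaustive triangle enumeration.

Activity is the weighted mean of signed, z-scaled target expression:
$a_{ds} = \sum_t \mathrm{sign}_t w_t z_{ts} / \sum_t w_t$. Expression is
z-scaled before weighting — the reference implementations do not document
this point, but without it activities are dominated by high-variance
targets and are not comparable across drivers; normalizing by
$\sum_t |w_t|$ keeps activities on the z scale (invariant to rescaling
all weights). Differential activity reuses the moderated two-group
machinery verbatim, and the hidden-driver filter keeps drivers with
$Z_{DA} > 1.96$ and $Z_{DE} < 0$: significant activity shifts without
elevated expression of the driver itself. The result is ranked by
$Z_{DA}$; an ordering by mean activity is attached alongside, since both
orderings are in use in the field.

## Enrichment

`gsea()` is the classic weighted running sum: hits rise by
$|s|^{w}$ (normalized over set members; `weight_exponent = 1` by default,
0 gives the unweighted Kolmogorov–Smirnov form), misses fall by
$1/(N - n_{set})$, and ES is the extremum. The null permutes gene labels,
not phenotypes, because callers pass a single precomputed ranking; NES
divides ES by the mean |ES| of same-sign permutations and `p_perm` is
one-sided within the same-sign permutations. A two-sample KS p-value on
the in-set vs out-set rank positions is always reported as well, since it
is exact, fast, and the quantity most often quoted for signature-level
comparisons; at exponent 0 the permutation p and the KS p agree within
Monte-Carlo error, which the tests exploit. Signed regulons are scored as
two separate sets (positive and negative targets): for a driver more
active in the cases at the top of the ranking, positive targets enrich at
the top and negative targets at the bottom. Gene-set activity for
signature panels (e.g. inflammatory M1 vs anti-inflammatory M2 macrophage
programs) is the unweighted mean of member z-scores, feeding the same
differential-activity machinery.

## The synthetic cohorts

The generators *define* the conditions under which the pipeline's
recovery and calibration claims are made, so their defaults are fixed and
documented rather than tuned per experiment.

`simulate_cross_species_cohort()` draws expression directly on the
log2-CPM scale — Gaussian per-gene noise around shared baselines
(log-normal expression), which matches what the DE stage consumes and
avoids an unneeded count layer; `as_counts()` provides a Poisson-thinning
export for exercising the raw-count entry point. Defaults: 2,000 genes;
a 40-gene shared response signature; 20 samples per group per species; a
species batch offset of 2 (removed by within-species z-scaling); noise SD
0.5. One designated driver gene carries the full `effect_size = 3`; the
other signature genes carry 30% of it with random signs. This two-tier
structure mirrors a single top driver standing atop a broader response
signature, and it is statistically necessary: with a uniform effect, the
±8.21 Z cap ties all strong genes at the top of the Stouffer ranking and
"the planted driver ranks first" would be decided by tie-breaking rather
than by signal. Mouse gene symbols differ from human ones only by case,
exercising the ortholog-matching path. Each emitted matrix derives its
RNG substream from the master seed by a fixed offset, so artifacts are
independently reproducible.

`simulate_regulon_population()` (defaults: 500 genes, 2 drivers × 20
targets, 40% negative targets — echoing the 30-positive/20-negative split
of a published immunotherapy-response regulon — 250 samples per group,
target noise SD 0.3) draws a latent activity per driver and sample;
positive targets read $+a$, negative targets $-a$, plus noise. The first
driver is planted as a *hidden* driver: its latent activity is shifted by
`driver_effect = 2` between groups, while its own mRNA tracks only the
within-group activity fluctuation and carries a small negative group
shift ($-0.15 \times$ `driver_effect`). That makes the driver's mRNA
informative for MI network inference (it covaries with its targets) yet
differentially *inactive* at the expression level — the phenocopy of a
post-transcriptionally activated driver. Additional drivers act as
decoys: unshifted activity with mildly elevated mRNA, the pattern the
hidden-driver filter must reject.

What the generators do **not** emulate: count-level sampling noise and
library-size variation (beyond the optional Poisson export), dropout and
zero inflation of real single-cell data, copy-number structure,
correlated background genes, and cell–cell communication. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under a clean log-normal model, not robustness to every pathology of real
data.

## Problem sizes and numerical conventions

The validation suite runs the d0 = 0 oracle on 1,000 random genes, the
Fisher-overlap enumeration over every configuration with universe ≤ 25,
null calibration on a 10,000-gene cohort and 2,000 random gene sets
(KS calibration uses 200 genes with sets of 40, where the exact
two-sample KS distribution applies), one full network-recovery run at the
generator defaults, 100-seed chain-pruning and 50-seed end-to-end
recovery loops — sizes chosen so the whole suite completes in minutes on
one core while keeping Monte-Carlo error well inside the asserted bands.

Degenerate inputs follow fixed conventions rather than errors where a
sensible value exists: constant genes get $p = 1, z = 0$ (flagged);
constant vectors have MI 0; zero-variance rows z-scale to 0; an empty
anchor set is a warning and a valid empty signature; a regulon with no
present targets is omitted with a warning. Hard errors are reserved for
contract violations: all-zero library columns, duplicate identifiers,
missing anchor genes, groups that do not partition the samples, a
universe smaller than the union of the tested sets.

## Known limitations

The MI estimator is the plug-in on quantile bins — adequate at the
sample sizes simulated here, biased upward at small $n$; the network
layer is not intended for thousand-node interactomes at single-cell
scale. The ortholog default is symbol identity, not a homology database.
The moderated model covers two groups without covariates; multi-factor
designs are out of scope. The "94%"-style headline numbers of published
cohort analyses depend on controlled-access datasets and are not
reproduced here; the package's claims are the property-based ones its
tests compute.
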