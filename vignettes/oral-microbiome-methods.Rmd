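---
title: "Models and methods behind oralsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oralsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

oralsite analyses paired saliva / buccal-mucosa 16S communities from an ASV
count table onward. This vignette explains the statistical models the
package implements, the choices that were genuinely open, and what the
synthetic generator does and does not emulate — so that a reader can judge
what a passing test suite shows about real data.

## Table preparation

The preparation rules are the common QIIME2-era conventions:

* A **singleton** is a feature whose total count across the merged study is
  1 (not per sample). Singletons are removed before leveling.
* The **leveling depth** is `floor(0.95 × minimum per-sample total)`.
  Rarefaction is a single seeded uniform subsample without replacement per
  sample; samples below the depth are dropped with a warning, never padded.
  Whether leveling should use one draw or average many is a known open
  point; a single seeded draw keeps every downstream quantity exactly
  reproducible, and none of the package's conclusions depend on the draw.
* Rank collapse sums counts over the lineage prefix; features unassigned at
  the requested rank (or missing from the taxonomy) are pooled into an
  `Unassigned` bucket so per-sample totals are conserved exactly.

## Diversity

Shannon entropy uses base 2 by default (bits); Chao1 is the bias-corrected
estimator `S + F1(F1−1)/(2(F2+1))`; Simpson is the Gini–Simpson index
`1 − Σp²`. These are authored in the package (the exact variants matter for
comparability), and the test suite cross-checks them against both
brute-force formula evaluation and vegan's implementations.

Group contrasts use Welch's unequal-variance t-test. The underlying study
design says only "t-tests"; Welch is the robust default and the choice is
documented rather than claimed. Group values are reported as mean ± SE
(SD/√n). The dominant-taxa table reports raw p values with significance
stars at 0.01/0.001; a Benjamini–Hochberg column is added as a clearly
labelled extension, because ten simultaneous raw t-tests overstate
certainty.

NMDS (via `vegan::metaMDS`) minimizes Kruskal stress-1 with a classical
scaling start and random restarts. Coordinates are defined only up to
rotation and reflection, so all tests on ordination output use
rotation-invariant quantities (distances between embedded points), never
raw coordinates.

## Sloan neutral community model

The neutral model predicts a taxon's occupancy (fraction of samples where
it is detected) from its metacommunity mean relative abundance `p` through
a beta-distributed local abundance with parameters `Nm·p` and `Nm·(1−p)`.
Only the product `Nm` (community size × immigration rate) is identifiable
from occupancy data, so the package fits that product directly.

Two detection models are offered:

* `detection = "limit"` (default, the classical form): a taxon is detected
  when its local relative abundance exceeds a hard limit `d`, by default
  `1/depth` after leveling — the smallest detectable abundance. Predicted
  occupancy is `1 − B(d; Nm·p, Nm·(1−p))`.
* `detection = "reads"`: the exact probability of drawing at least one read
  at depth `D`, `1 − B(Nm·p, Nm·(1−p)+D)/B(Nm·p, Nm·(1−p))`. The two agree
  when `D ≫ Nm`; when they do not, the hard-limit form is biased because
  read-level detection smooths the occupancy curve and the fit absorbs the
  smoothing into `Nm`. Parameter-recovery studies in the test suite use the
  read-level form for this reason; the default stays with the classical
  form for comparability with published fits.

`Nm` is estimated by grid-started nonlinear least squares (minpack.lm).
Numerical choices: the start grid spans `10^-1`–`10^7` in quarter-decades;
when the NLS step cannot improve on the grid (constant occupancy makes the
objective flat), the grid optimum is returned and an undefined `R²` is
reported as a poor fit rather than an error.

The confidence interval for `Nm` is a parametric basic bootstrap: data are
re-simulated from the fitted model at the observed depths, re-estimated,
and the pivot interval taken. This was chosen over the usual Wald interval
from the NLS standard error because occupancy residuals are heteroskedastic
binomial and, at low `Nm`, the estimated abundances `p̂` of rare taxa are
noisy, which attenuates the fit; the parametric bootstrap reproduces both
effects and corrects the first-order bias. The interval is widened, if
necessary, to contain the point estimate.

The 95% band around the fitted curve — which drives the above/fit/below
partition — combines exact binomial quantiles of occupancy at `n` samples
with the variance of `p̂` propagated through the curve slope. A plain
Wilson band around the prediction misclassifies the `F ≈ 1` boundary
(`F_obs = 1` is a typical draw from `Binomial(n, 0.99)`) and calls noisy
rare taxa non-neutral purely because their abscissa is uncertain.

## Null model and deterministic strength

Observed β diversity is the mean pairwise Bray–Curtis within a group. The
null ensemble scrambles which taxa occur where while preserving, exactly
and per draw: each sample's richness and read total, and each taxon's
occupancy count. Presences are randomized by vegan's curveball (fixed-fixed)
algorithm; abundances are refilled by giving every present taxon one read
and distributing the remainder multinomially in proportion to group-wide
(regional) abundance. `ses.beta = (obs − mean null)/sd null`.

Deterministic strength summarizes, per sample pair, the relative departure
of observed dissimilarity from its null mean: `(d_obs − d_null)/d_obs` when
observed exceeds the null (heterogeneous selection), `(d_null − d_obs)/d_null`
otherwise (homogenizing selection); DS is 100 × the mean over pairs. The
source literature for DS gives no equation, so this selection-strength form
is an explicit implementation choice of this package: published DS values
can be emulated directionally (neutral assemblies score lower than
habitat-filtered ones; DS grows monotonically with filter strength) but not
matched numerically. Pairs with zero observed *and* zero null dissimilarity
carry no signal and are skipped with a warning; a pair with zero observed
but positive null dissimilarity is maximal determinism (strength 1).

## Random-forest habitat classification

The procedure is: stratified 70/30 split, impurity-importance ranking of
all features on the training side only, refit on the top 30, resubstitution
and held-out accuracy. Hyperparameters (500 trees, default mtry) are desk
choices; the source procedure names none.

The split offers two modes. The default stratified sample-level split
mirrors the published procedure. `individual_aware = TRUE` splits whole
subjects, and is the statistically sound evaluation for a *paired* design:
with sample-level splits, the held-out twin of a training sample carries
the opposite label, so a forest that recognizes the individual is pushed
*against* the true label — under identical habitat profiles this
anti-learning drives accuracy far below 50%, and under real effects it
deflates accuracy below the classifier's ability. The package's calibration
tests therefore use the grouped split for both the null case (accuracy
compatible with guessing) and the effect case.

Leakage is tested directly: perturbing test-sample counts must leave the
training-side importance ranking bit-for-bit unchanged.

## Personal discrimination

Unique species are sought among species ranked strictly outside the top 100
by overall mean relative abundance; a species is unique when its presence
(any nonzero count) is confined to one individual's samples, with no
abundance floor. If fewer species than the threshold exist, every species
becomes a candidate and a warning is raised. Ranking can be restricted to
one habitat (the default analysis ranks per habitat) or pooled.

The core microbiome is the set of genera with a nonzero count in at least
one sample of *every* individual; the `Unassigned` bucket is not a genus
and is excluded. The microbial code restricts an individual's mean
relative-abundance profile (per habitat) to the core genera and
renormalizes to sum 1; codes are invariant to sequencing depth by
construction. Matching is Bray–Curtis, ascending, ties broken by reference
id.

## The synthetic generator

The generator is the package's ground truth and emulates the study design:
50 subjects, one saliva and one mucosa swab each, per-sample read depths
uniform on 50,201–199,533, and the published genus-level composition table
as the default profiles.

**Composition model.** Named genera carry both a group mean and a
between-subject standard deviation per habitat (taken from the published
mean ± SE table where stated; the eight core genera outside that table get
CV 1.2, the scale of comparable-abundance genera in it). A subject's
composition is a Connor–Mosimann generalized Dirichlet over genera: stick
`i` takes a Beta fraction of the remaining mass, and the Beta parameters
are solved recursively by moment matching so that *every genus's
post-normalization mean and SD equal the configured values exactly*. A
symmetric Dirichlet cannot do this (one concentration cannot serve both a
genus at 50% and one at 1%), and independent gamma multipliers match
dispersion only before normalization, compressing the dominant genus's SD
by a third.

**Pairing.** The stick draws are realized from per-subject uniforms shared
between the two habitats (common random numbers), so one subject's saliva
and mucosa are coupled — the basis for microbial-code matching — while each
habitat's marginal distribution is untouched.

**Species layer.** Each named genus splits into two species. The split is
habitat-specific for the five dominant genera (70/30 in saliva, 58/42 in
mucosa) with per-subject Beta(κ = 25) jitter: species-level differential
abundance exists beyond genus shifts, as the species-level analyses of
paired oral cohorts report, and a fixed split would make the species ratio
a deterministic — hence implausibly perfect — classifier feature. Genus
marginals are unchanged by construction.

**Rare tail and occupancy.** Beyond the named genera, a truncated
log-series tail (default 300 species, each its own genus) absorbs the
remaining mass — saliva carries more tail mass, hence its higher evenness.
Tail occupancy rises with abundance (0.5 for the rarest to 0.85 for the
most abundant tail taxon), the usual occupancy–abundance relationship;
absent taxa are compensated by 1/occupancy so cohort means stay at the
profile. The cap at 0.85 keeps any tail genus from plausibly appearing in
all 50 subjects, so the 16 flagged core genera are exactly the core at
study scale.

**Core guarantee.** Core-flagged taxa are floored at relative abundance
3×10⁻⁴ within every sample (then renormalized), with a one-read repair as
backstop, so the planted core survives leveling — a construction oracle for
the core-detection stage.

**Neutral and filtered modes.** `simulate_neutral_assembly` draws each
taxon's local abundance from the Sloan beta around the metacommunity mean
and then multinomial reads — the exact generative model the read-level NCM
fit assumes. `simulate_filtered_assembly` splits samples between two
sub-habitats whose profiles are interpolated between the pooled mean
(strength 0) and the two configured profiles (strength 1), giving a pure
deterministic dial for null-model experiments.

**What is not emulated.** Sequencing error, chimeras, primer artifacts,
compositional correlations beyond the genus sticks, strain-level variation,
age or sex effects (metadata age/sex are exchangeable decoys), and the
~58,000-ASV feature richness of real runs (the desk-scale namespace is
~340 species). Passing tests therefore show the *methods* behave correctly
under the study's statistical structure; they do not certify performance on
real sequencing artifacts.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale: neutral-model
recovery uses 20 replicates of 100 samples × ~300 taxa across
`Nm ∈ {100, 1000, 10000}` with 49 bootstrap draws; null models use 15–16
samples with 99 randomizations; classifier calibration uses 100 null and 20
effect replicates of the full 50-subject design; the pipeline determinism
check runs a reduced cohort twice. All randomness flows from one master
seed through named substreams (`substream_seed`), so each stage is
reproducible in isolation and two pipeline runs from one seed are
byte-identical.

## Known limitations

* The generalized-Dirichlet moment matching is exact for genus means and
  SDs but inherits mild distortion in the last, tiniest tail sticks where
  the variance targets are clamped to feasibility.
* The hard-limit NCM fit is biased when depth is not much larger than `Nm`;
  use `detection = "reads"` when the estimate itself matters.
* DS has no canonical formula; values are comparable within this package
  only.
* The unique-species rule has no abundance floor, so a single stray read
  confined to one subject counts as unique; on real data a floor or
  prevalence filter may be advisable.
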