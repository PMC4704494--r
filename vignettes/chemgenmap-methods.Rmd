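---
title: "Methods: multiparametric chemical-genetic interaction mapping"
author: "chemgenmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric chemical-genetic interaction mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemgenmap)
```

# The problem

High-content compound screens across panels of isogenic cell lines ask a
simple question with a heavy statistical footprint: for which (compound,
genotype) pairs does the cellular phenotype deviate from what the compound
effect and the genotype effect would produce independently? Such deviations
— chemical-genetic interactions — point at the pathways a compound engages,
reveal off-target activities, and suggest synergistic drug combinations. The
phenotype is deliberately multiparametric: besides cell number, image-derived
descriptors of nuclear and cellular morphology, intensity and texture carry
most of the signal, and many interactions never touch growth at all.

`chemgenmap` implements the full desk-side pipeline: synthetic-data
generation with known ground truth, image segmentation and feature
extraction, feature preprocessing and selection, interaction estimation and
testing, profile-level analyses, and combination/synergy statistics. The
numbered scripts under `analysis/` narrate one pass through the pipeline and
write their tables under `results/`.

# The model

Well-level feature values are analysed on a generalized-log scale,
`glog(x; c) = log2((x + sqrt(x^2 + c^2))/2)`, which is logarithmic for large
`x`, linear near zero and defined at zero. The calibration constant `c`
defaults to 1 for count-like features; the transform is exactly invertible
(`glog_inverse()`).

For each feature and replicate, wells are collapsed to one value per
(compound, cell line) by the median, giving a compounds x lines matrix `M`.
Tukey's median polish decomposes

```
M[d, c] = m + a[d] + b[c] + pi[d, c]
```

by alternately subtracting row and column medians until the relative change
in the sum of absolute residuals falls below `1e-4`. The row values `a` are
compound effects, the column values `b` cell-line effects, and the residuals
`pi` are the interaction coefficients — a robust L1 analogue of a two-way
ANOVA in which a sparse set of true interactions cannot drag the main
effects. A negative cell-number coefficient means a genotype-specific growth
defect. Cell-number values are first rescaled per cell line so that the
median of the vehicle wells maps to 1 and the strong-kill reference compound
maps to 0 (values outside [0, 1] are allowed); this removes the baseline
proliferation differences between the isogenic lines.

Replicate coefficients are tested against zero with an empirical-Bayes
moderated one-sample t: each unit's variance is shrunk toward a prior,
`s~^2 = (d0 s0^2 + (R-1) s^2)/(d0 + R - 1)`, and the statistic
`t = mean/(s~/sqrt(R))` is referred to a t distribution with `d0 + R - 1`
degrees of freedom. The hyperparameters are fitted by moment matching on the
log sample variances using the closed-form digamma/trigamma identities of
the scaled-F model. P-values are Benjamini-Hochberg adjusted per feature
across all (compound, line) units of that feature's interaction matrix, and
interactions are called at FDR 0.01.

## Prior scope with two replicates

With `R = 2` each unit contributes a single residual degree of freedom and
the per-feature moment estimator of `d0` (a few hundred units) is very
unstable — occasional tiny `d0` estimates put the reference distribution on
3-4 degrees of freedom, where even |t| near 20 fails a 1% FDR. The package
therefore fits one prior `d0` across the units of *all* features and gives
each feature its own prior scale: sample variances are standardised by the
feature's median variance before pooling, and the fitted `s0^2` is rescaled
back per feature. The per-feature scale matters because the range-normalised
cell number lives on a different measurement scale than the glog features;
pooling raw variances across such features inflates the apparent
between-unit variance heterogeneity and collapses `d0`. `prior_scope =
"feature"` restores the per-feature fit for large screens.

A genuine property of median-polish residuals is worth knowing: the L1 fit
interpolates a subset of cells exactly (residuals identically zero), so
residual variances are truly heterogeneous across cells and the fitted `d0`
is finite even when the measurement noise is homoscedastic. This is not an
estimation artifact; it caps the degrees-of-freedom gain the moderation can
deliver at desk scale.

# Image processing

Two-channel (DNA, actin) well images are processed as: optional border crop
(default margin 150 px for 2048 px acquisitions); nuclei segmentation by
local-mean adaptive thresholding with a 10 x 10 px window and a small
positive offset (blank images yield no foreground), hole filling and
connected-component labelling; cell segmentation by Voronoi-based
propagation of the nuclear seeds into an adaptive threshold mask of the
actin channel (window 50 px, union with the nuclei so every seed is
covered). The propagation guarantees one cell region per nucleus, disjoint
regions, and the partition of any actin blob shared by several nuclei. Per
cell, shape (area, perimeter, equivalent radius, eccentricity), intensity
statistics and Haralick textures (32 grey levels, 1 px offset, directions
averaged) are computed for the nucleus on the DNA channel and for the cell
body on the actin channel; wells are summarised by the number of segmented
nuclei (the cell-count proxy) plus per-feature means, with cell-to-cell
standard deviations for intensity features. The segmentation and feature
numerics are delegated to EBImage, the toolkit this class of screens is
built on; the module's contracts (label counts, partition properties,
geometric feature values) are what the tests pin down.

# Feature selection

Replicate reproducibility is summarised by per-feature correlation between
replicates (Pearson by default; Spearman available — the two conventions
coexist in the screening literature and differ little on glog data).
Informative, non-redundant features are selected stepwise, starting from
cell number: each candidate is regressed (OLS with intercept, fitted within
each replicate separately) on the already-selected features, and scored by
the correlation between the two replicates' residual vectors — reproducible
variance not yet captured. The best candidate is selected; the procedure
stops when the percentage of positive residual correlations over all
features drops below 50%.

Two reading choices deserve a note. First, the residual correlation is
computed per replicate and then correlated across replicates (not pooled),
so purely technical within-replicate structure cannot masquerade as signal.
Second, the stopping fraction is computed over *all* features, with
already-selected features (whose residuals are exactly zero, hence an
undefined correlation) counting as not positive while staying in the
denominator. Counted over candidates only, the null stopping fraction sits
exactly at 1/2 and termination becomes a coin flip; over all features the
procedure stops reliably once the informative span is exhausted, which is
the behaviour the selected-count benchmarks exercise.

Selected features map to the five phenoprint categories (cell number, DNA
texture/intensity, nuclear shape, cell shape, actin texture/intensity) by a
name-pattern default, and `group_phenoprint()` lays them out for radar-chart
display with radial distance proportional to the feature value.

# Profile-level analyses

Compound profiles are the pooled (replicate-mean) interaction coefficients
flattened over (line, feature) cells, in three views: `genotypes_only`
(cell number across lines), `phenotypes_only` (all features in a reference
line) and `combined`. Dissimilarity is `1 - cor` (Pearson); clustering is
complete-linkage; reported clusters sit below a 0.6 height cut with more
than 2 and fewer than 10 members. The interaction map is a bipartite
genotype-compound graph built from the significant calls after removing
controls, compounds hitting more than three genetic backgrounds, and
compounds affecting fewer than two features.

The resolution index quantifies how well profile correlations separate
compound pairs that share target selectivity (or chemical structure,
Tanimoto distance strictly below 0.6) from pairs that do not: the ECDF of
pair correlations is computed per class and the index is the difference of
the exact step-function integrals over [-1, 1] (non-shared minus shared;
for a sample inside the interval this equals `1 - mean(x)`, so the index is
the difference of class means — positive when shared pairs are more
correlated). Signed correlations are used: the index is meant to capture
the rightward ECDF shift of the shared class, which absolute values would
distort.

The benchmark generator for this analysis (`gen_profile_set()`) plants, per
mode-of-action class, a rank-1 genotype x morphology interaction pattern
spanning every (line, feature) cell, adds compound-specific nuisance only in
the two marginal readouts (the cell-number row and the reference-line
column), and i.i.d. noise everywhere. This encodes the mechanism by which
the combined view wins: single-view readouts are contaminated by residual
compound-level potency effects, while the full interaction pattern is
class-determined. On this generator the combined view's index exceeds both
single views in essentially every seeded run.

# Combinations and the proteasome statistic

Plate-reader viability values are log-transformed (natural log; the base
cancels) and anchored on the plate controls:
`NPI = (mean log pos - log x)/(mean log pos - mean log neg)` and the effect
is `E = 1 - NPI`, so `E = 0` at the untreated level and `E = 1` at full
kill. (The historical name "normalized percentage inhibition" is kept even
though the formula as printed is 1 at the untreated control; the package
works with `E` throughout.) Under Bliss independence
`E_AB = E_A + E_B - E_A:B` with `E_A:B = 0`; the interaction term is
estimated per dose by plugging in the arm means, so synergy (stronger than
independent killing) appears as `E_A:B < 0`. The null `E_A:B = 0` is tested
per dose by a Welch two-sample t comparing the combination-effect replicates
with single-agent sums paired by replicate index; this uses all stated
replicate counts (at least 10 combination and 20 single-agent measurements
per dose) and has the correct variance `var(E_A) + var(E_B)` under
independent arms. A one-sample plug-in variant is available. The simulated
grids default to 32 control wells per control type (two full 384-well
columns); with much smaller control sets the shared normalization noise is
no longer negligible relative to the arm variances and the test runs
slightly hot.

Proteasome inhibition is `100 * (1 - (PT/PC)/(VT/VC))`: the
treated/control activity ratio corrected by the treated/control viability
ratio, so vehicle gives 0%, complete inhibition 100%, and proportional
(purely cytotoxic) loss 0%. Replicates are tested one-sided against zero;
zero-variance inputs report the limiting statistic with a warning.

# The synthetic screen generator

The generator is first-class, tested code and defines the study conditions.
A screen design places each (cell line, replicate) on its own 384-well (or
96-well) plate series with vehicle, strong-kill reference and
pathway-reference control wells on every plate and one well per compound per
series, extending to more plates as needed (the reference configuration
emulates a 1,280-compound x 12-line x 2-replicate screen at 5 uM; the
analysis drivers run a 50 x 8 x 2 screen). Feature values follow the
additive model on the glog scale — baseline + compound effect + line effect
+ sparse interaction + Gaussian noise — with compound and line effect sd
0.5, planted interactions of magnitude 0.5-2 (random sign) on 2% of cells,
and noise sd 0.2; the kill reference suppresses cell number by 3 glog units.
Gaussian noise on the glog scale is the natural choice because the analysis
assumes symmetric residuals after variance stabilisation. Rendered well
images place non-overlapping elliptical nuclei inside larger (optionally
elongated) actin bodies with configurable radii, intensities and speckle
texture; packing failures raise an error rather than silently overlapping
cells. Blank "bad" wells (zero cells, zero intensity) can be injected for
QC testing; the QC rules (flag empty-and-dark wells, and saturation above
5% where a saturation column exists) are the package's own defaults, not a
claim about any particular instrument's criteria.

What the generator does not emulate: optics (point-spread functions,
illumination gradients), plate-position effects, batch structure,
heavy-tailed or count-valued noise, and biologically structured feature
correlations beyond the planted model. Passing tests therefore demonstrate
that the statistical machinery recovers what it is designed to recover
under its own assumptions, not that those assumptions hold on any given
instrument's data.

# Numerical choices and edge cases

* Median polish: medians of even-length vectors are the mean of the two
  central order statistics; missing entries are ignored by the medians;
  all-missing rows or columns are an error; convergence is `|dS|/S < 1e-4`
  (configurable), with the reconstruction identity holding to machine
  precision at any stopping point. Whole-row shifts are absorbed exactly;
  whole-column shifts are absorbed up to the path dependence of the
  alternating iterate (L1 fits are not unique), which can move individual
  residuals by a few hundredths.
* Variance-prior fitting floors sample variances at `1e-5 x median` before
  taking logs, handles the all-zero case with an infinite-d0 epsilon prior
  and a warning, and inverts the trigamma function by Newton iteration.
* Stepwise selection breaks score ties lexicographically and drops
  collinear predictors with a warning, so it is fully deterministic.
* Undefined correlations (constant profiles) are flagged and excluded from
  the resolution index with a reported count.
* Structure-similarity classification uses a strict `< 0.6` cutoff (a pair
  at exactly 0.6 is "different structure").
* Complete-linkage ties resolve to the lowest-index merge (the `hclust`
  convention), making cluster extraction permutation-equivariant.

# Problem sizes

The bundled analyses and tests run at desk scale, chosen so a full pass
stays within a couple of minutes on one core: the reference screen is 50
compounds x 8 lines x 2 replicates x 10 features; the selection benchmark
uses 500 wells x 100 features over 20 seeds; FDR calibration uses 100 null
screens; combination calibration uses 500 null grids. At this scale the
recovery of planted interactions has a noise floor worth stating: with
noise sd 0.2, two replicates and an 8-line panel, the pooled median-polish
residual at a planted cell has standard deviation close to 0.16 (the L1
row/column medians add roughly `pi/(2L) + pi/(2D)` relative variance to the
`sigma/sqrt(2)` pooled noise), so the root-mean-square recovery error of
planted coefficients sits near 0.16 — an intrinsic property of the robust
decomposition at this panel width, not an implementation defect; a
mean-based two-way fit would reach about 0.13 but would lose the robustness
that motivates the median polish.

# Known limitations

* The per-feature BH adjustment mirrors the screen-analysis convention;
  adjusting across features would be more conservative and is not exposed.
* The moderated test assumes exchangeable units within a feature;
  spatially structured plate effects would violate this and are neither
  simulated nor corrected.
* The imaging module targets the synthetic rendering regime (well-separated
  blobs, moderate texture); densely confluent real images would need
  watershed-style splitting that is out of scope.
* Chemical fingerprints are consumed as a precomputed distance matrix; the
  package never computes structural similarity from molecular structures.
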