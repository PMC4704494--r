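# chemgenmap

Multiparametric chemical–genetic interaction mapping from high-content
screens, for computational biologists analysing compound screens across
panels of isogenic cell lines. The package covers the whole desk-side
pipeline — synthetic screens with known ground truth, two-channel image
segmentation and feature extraction, feature preprocessing and stepwise
selection, median-polish interaction scoring with empirical-Bayes moderated
t-tests, profile clustering and the resolution index, and Bliss-independence
combination scoring plus a viability-corrected proteasome inhibition
statistic.

## The model

Well-level features on a generalized-log scale,
`glog(x; c) = log2((x + √(x² + c²))/2)`, are collapsed per feature and
replicate to a compounds × lines matrix `M` and decomposed by median polish:

    M[d, c] = m + a_d + b_c + π_dc ,

where row and column medians are subtracted alternately until `|ΔS|/S <
1e-4` (`S` the sum of absolute residuals). The residuals `π_dc` are the
chemical–genetic interaction coefficients; a negative cell-number
coefficient signifies a genotype-specific growth defect. Cell numbers are
first rescaled per line so the vehicle median maps to 1 and the strong-kill
reference to 0. Replicate coefficients are tested against μ = 0 with a
moderated one-sample t — per-unit variances shrunk toward an
empirical-Bayes prior, `s̃² = (d₀s₀² + (R−1)s²)/(d₀ + R − 1)`,
`t = x̄/(s̃/√R)` on `d₀ + R − 1` df — and Benjamini–Hochberg adjusted per
feature, with calls at FDR 0.01. Compound profiles (pooled `π` over lines ×
features) are compared by `1 − cor`, clustered with complete linkage, and
benchmarked by the resolution index ΔAUC: the difference of the exact ECDF
integrals over [−1, 1] of profile correlations between compound pairs that
do not and do share target selectivity (or chemical structure, Tanimoto
distance < 0.6). Drug pairs are scored per dose under Bliss independence,
`E_AB = E_A + E_B − E_A:B` on control-anchored log-scale effects, with
synergy appearing as `E_A:B < 0`; proteasome inhibition is
`100·(1 − (PT/PC)/(VT/VC))`.

## Worked example

The numbered scripts under `analysis/` run one pass over a simulated
reference screen (50 compounds × 8 isogenic lines × 2 replicates, 10
features, 80 planted interactions of magnitude 0.5–2 at noise sd 0.2):

```sh
Rscript analysis/01_simulate_screen.R
Rscript analysis/04_score_interactions.R
```

prints

    screen: 1120 wells on 16 plates; 10 features; 80 planted interactions
    QC: 0 + 0 wells flagged
    significant interactions at FDR 0.01: 65
    per genetic background:
    line_01 line_02 line_03 line_04 line_05 line_06 line_07 line_08
         10      11       4      11       6      10       5       8
    planted recovery (72 cells): sign agreement 1.000, RMSE 0.159
    planted cells called significant: 0.806

i.e. every recovered interaction coefficient carries the planted sign, the
recovery error sits at the L1 noise floor of the 8-line panel (≈0.16; see
the methods vignette), and 81% of planted cells — 97% of the strong ones —
are called at FDR 0.01 with zero calls in matched null screens. The other
drivers exercise the imaging branch (planted cell counts of 30/18/12/15 are
segmented exactly), feature selection (exactly the 20 planted signal
dimensions are selected out of 100 features), the profile map
(ΔAUC: combined 0.707 vs genotypes-only 0.225 and phenotypes-only 0.205),
and combinations (a planted Bliss term of −0.15 is detected at all 10
doses; a proteasome inhibitor-like condition scores 50.2% inhibition,
one-sided p = 4.7e-08, while a purely cytotoxic condition scores 2.7%,
p = 0.2).

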