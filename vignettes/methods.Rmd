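---
title: "Quantifying compression effects in brain organoids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compression effects in brain organoids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoquant)
```

# Scope

`mechanoquant` implements the quantitative chain that links mechanical
compression of brain organoids to neural-stem-cell readouts: rheometer
force-trace analysis, per-pixel immunofluorescence quantification of
organoid sections with apico-basal binning, and transcriptomic scoring
(pathway transcriptional deviation, gene-set activity, QC and enrichment
filters). Every stage is exercised on synthetic data with recorded ground
truth, generated by the package itself, so each estimator's recovery
properties can be checked without any external dataset. The `analysis/`
scripts run the full chain end to end; the test suite asserts the recovery
guarantees stated below.

# Mechanics

An organoid of initial height $X$ (the first recorded gap; contact
detection from the trace is deliberately not attempted) is compressed in
$n$ cycles. In strain mode ("compressed **by** a level $\lambda$") the
compressed height is $Y = X(1-\lambda)$; in residual mode ("compressed
**to** $\lambda$") it is $Y = X\lambda$. Strain mode is the default — it is
the phrasing that describes the experimental protocol — and the two
conventions coincide at $\lambda = 0.5$. Cycles are segmented on the gap
channel, not the force channel, because the gap is the prescribed control
variable: a cycle is a maximal excursion of the gap below
$X(1 - \texttt{tolerance})$, with a 5 % default tolerance band. The mean
maximum peak force is the arithmetic mean of the per-cycle force maxima,
and the nominal stress assumes a circular undeformed cross-section of
diameter $d$:

$$\sigma = \frac{F}{\pi (d/2)^2}.$$

Reported integer-pascal values truncate toward zero; with $d = 3$ mm this
maps 2 mN to 282 Pa and 14 mN to 1980 Pa (the untruncated values are
282.9 and 1980.6 Pa). Cycle-to-cycle peak correlations (Pearson) test
whether viscoelastic peak decay is consistent across organoids, and an
ordinary least-squares regression with a two-sided slope test relates mean
maximum peak force to mean marker intensity per organoid; the regression
accepts either whole-section or VZLS-restricted intensity vectors.

The trace generator produces triangular gap excursions with rest phases at
$X$ between cycles and a force that follows $F_i \cdot \mathrm{depth}^2$
within cycle $i$, so the noiseless per-cycle force maximum equals the truth
peak exactly (the sampling grid always contains the gap minimum). Default
peaks decay across cycles (10, 8, 7 mN), emulating viscoelastic
relaxation; peak magnitudes sit in the 2–14 mN range the compressions
span. This is a phenomenological waveform: no constitutive viscoelastic
model is implied, and the generator does not simulate the instrument's
control loop.

# Section quantification

A section is an integer label map (0 background, 1 neuronal compartment
NC, 2..k+1 VZLS) plus ordered boundary polylines: one apical (lumen-facing)
and one basal contour per VZLS and one outer organoid contour. Geometry is
0-based `(row, col)` with pixel centres at integer coordinates and
Euclidean distances in µm. Every polyline is densified to at most 0.5 px
point spacing before querying, which bounds the discretisation error of a
point-to-curve distance by a quarter pixel; distances are nearest-point
searches against the densified set. The compiled search kernel is
contractually equal to exhaustive all-pairs search and the test suite
asserts bit-identical agreement with a pure-R exhaustive oracle on random
sections.

The apico-basal position of a VZLS pixel is
$\rho = d_\text{apical}/(d_\text{apical}+d_\text{basal}) \in [0,1]$.
Two binning modes exist because both conventions are in use: ten equally
sized relative bins (`bin = floor(10 rho)`, bin 0 most apical, $\rho = 1$
clamped into bin 9; the default), and absolute 20 µm bins of apical
distance measured per pixel. Pixels with
$d_\text{apical}+d_\text{basal}=0$ cannot be placed on the axis; they are
flagged, counted in a warning, and excluded from profiles rather than
silently binned.

Fold changes divide each organoid's mean intensity by the mean of the
uncompressed (ctrl + mock) reference group, within the matching bin when
binned, so the reference group's mean fold change is exactly 1 by
construction. Group contrasts use the two-sided Wilcoxon rank-sum test,
exact when the combined sample size is at most 20 (the regime of 4–20
organoids per condition where these comparisons live) and a
normal approximation with tie correction above that. No multiple-testing
correction is applied across bins or contrasts by default — the
per-contrast values are reported raw — with Benjamini-Hochberg available
behind a flag.

"Marker-positive" is operationalised per pixel, not per segmented nucleus:
positivity is an intensity threshold (Otsu's method on the in-scope
intensities by default, or a fixed value, always recorded in the output).
This is a deliberate simplification — only per-pixel measurement is
implemented upstream — and a known divergence risk against
nucleus-segmentation-based counts. Lineage fractions (e.g. BrdU/NEUN
double positives among BrdU positives) require the numerator marker set to
contain the denominator set; organoids with an empty denominator are
excluded with a warning rather than producing division by zero.

The section generator rasterises annular VZLS (apical = inner circle,
basal = outer circle) inside an organoid disc, the simplest geometry with
distinct apical and basal contours; a straight-walled "band" mode exists
for geometric sanity checks, with the band height chosen commensurate with
the default ten bins so a uniform band fills relative bins with equal
pixel counts. Noiseless intensity is
$\text{base} \times \text{fc}(\text{condition}) \times
(1 + \text{slope}\cdot\rho)$ for positive VZLS pixels, with NC positives
at half base and non-positive pixels at 8 % of base; noise is additive
Gaussian, clipped at zero. All randomness derives from a mandatory seed,
and geometry depends only on the truth seed, so sections generated for
different conditions from one truth share identical geometry — which makes
noiseless fold-change examples exact. The generator does not attempt
photorealism: no point-spread function, no nuclear texture, no
illumination gradients. Passing recovery tests therefore demonstrate
estimator correctness on the stated noise model, not robustness to real
microscopy artefacts.

# Bulk transcriptomics

Counts are normalised to counts per million; `log2(CPM + 1)` feeds
differential expression. The DE engine is deliberately generic — a
per-gene two-sided Wilcoxon rank-sum test on log-CPM with
Benjamini-Hochberg FDR — standing in for a GLM quasi-likelihood fit that
is out of scope here; the gates are
$p < 0.01$, $\text{FDR} < 0.01$, $|\log_2\text{FC}| > 2$. The
absolute-value reading of the fold-change gate is intentional (both up-
and down-regulated genes are reported); a one-sided option exists. Note an
arithmetic consequence of exact rank tests at small $n$: with 6 vs 6
samples the smallest achievable two-sided p-value is
$2/\binom{12}{6} \approx 0.0022$, which cannot survive an FDR threshold of
0.01 unless hundreds of genes are truly changed, so contrasts at that
depth should pool the reference groups (12 vs 6 gives
$2/\binom{18}{6} \approx 1.1\times10^{-4}$).

The pathway transcriptional-deviation score of pathway $P$ in sample $s$
is

$$D_{P,s} = \frac{1}{n_P} \sum_{g \in P \cap \text{dataset}}
\ln\frac{x_{g,s}+\varepsilon}{\mu_g+\varepsilon},$$

where $\mu_g$ is the mean CPM of gene $g$ over the uncompressed (ctrl +
mock) reference samples and $\varepsilon = 0.5$ CPM guards against zeros.
The reference defaults to ctrl ∪ mock with a switch for ctrl only.
Scores are computed per sample; grouping enters only through the one-way
ANOVA over uncompressed/comp50/comp60 with Tukey HSD post-hoc contrasts,
and each pathway is assigned a significance tier (`ns`, `50-only`,
`60-only`, `both`) from the two Tukey p-values at $\alpha = 0.05$. No
correction is applied across pathways by default.

Two properties of $D$ are worth keeping in mind when reading results.
First, $\ln$ of a noisy count underestimates $\ln$ of its mean (Jensen's
inequality); for negative-binomial counts with dispersion $\alpha$ the
bias is approximately $-\alpha/2$ per gene, shared across groups, so
group *contrasts* are unbiased while absolute scores are shifted slightly
negative. Second, CPM is compositional: strongly induced genes inflate a
sample's library and depress every other gene's CPM, shifting null
pathways negative in proportion to the induced genes' library share. The
bulk generator's defaults (2000 genes, dispersion 0.05 — a biological
coefficient of variation of ~0.22, typical for bulk RNA-seq biological
replicates — and 40-gene pathways, i.e. ~2 % library share per pathway)
keep both terms a few hundredths of a log unit, which is why an injected
ln-fold-change of 0.7 is recovered as ~0.65: the recovery tolerance of
±0.1 absorbs the closed-form bias. The `analysis/` driver prints the
compositional null-pathway shift explicitly so tier tables can be read
against it.

Term enrichment is the classic one-sided Fisher exact test per term — the
upper hypergeometric tail, computed via `phyper` and verified in the tests
against both `fisher.test` and an explicit `lchoose` enumeration — with
the filter $p < 0.05$ and at least 5 DE genes per term, and a top-15
reporting helper. No ontology-graph propagation is performed: terms are
flat gene sets read from GMT.

# Single-cell scoring

QC removes cells with fewer than 2500 detected genes, fewer than 5000 or
more than 25000 UMIs, or more than 7 % mitochondrial reads, then genes
expressed in fewer than 10 remaining cells. A cell failing several rules
is counted once per rule but removed once; the filter is idempotent.
Clustering, embedding, pseudotime and doublet detection are inputs, not
computations, of this package.

Gene-set activity per cell is the mean log-expression of the set's genes
minus that of an expression-matched reference pool: genes are ranked into
10 quantile bins of mean expression, and 50 reference genes per set gene
are drawn (seeded, without replacement, excluding the set itself) from the
matching bin. These three parameters are declared defaults rather than
library-internal constants precisely so the scores are reproducible; the
score of a random set is centred at zero by construction. Regulon activity
fold change normalises each cell's score to the mean score of uncompressed
cells in its cluster and tests conditions per cluster with a two-sided
Mann-Whitney U test; clusters missing a condition, or with a zero
reference mean (a real hazard for scores centred at zero — regulons worth
normalising have positive baseline activity), are skipped with a warning.
Score-versus-pseudotime trends are ordinary least squares per condition
with a percentile bootstrap (1000 seeded resamples of cells) for the 95 %
band; resamples with degenerate pseudotime variance are dropped.

The single-cell generator draws log-expression as Gaussian noise around
per-cluster gene baselines, adds planted (set, cluster, condition) shifts
and monotone pseudotime trends, and constructs QC covariates so that
exactly the requested number of cells violates each rule (violator sets
are disjoint, so per-rule counts are exact). Values are not truncated at
zero — unlike real log-normalised expression — which keeps shift-recovery
arithmetic exact; gene-floor violators are planted as exact zeros instead.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-scale sizes
chosen so each check completes in seconds while keeping Monte-Carlo noise
well inside the asserted tolerances: sections of 64–128 px (20 sections
for the exhaustive-oracle equality; 100 cohorts of 14 organoids for
fold-change recovery), 2000-gene bulk simulations with 6 samples per group
(100 seeds), single-cell simulations of 600–2000 cells and 300–500 genes
(100 seeds for cluster-specificity), and full enumeration of all
hypergeometric tables with margins up to 30. Seeds are mandatory
constructor arguments throughout; there is no hidden global RNG state, and
callers' RNG streams are never disturbed.

Known limitations: no real-image validation (boundaries are consumed as
given, never inferred); 2-D sections only; the Otsu positivity threshold
assumes an approximately bimodal intensity histogram and can land between
signal modes on strongly trimodal images (a fixed threshold is the
fallback); the deviation score inherits CPM's compositionality as
discussed; and the DE stage is a rank test, not a count-model fit, so its
power profile differs from GLM-based engines at very small $n$.
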