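---
title: "Methods: bar quantification and multiple-QTL mapping in barqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bar quantification and multiple-QTL mapping in barqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barqtl)
```

# Overview

`barqtl` implements a two-stage analysis. The phenotyping stage turns a
flank photograph into a one-dimensional grayscale intensity profile, calls
dark vertical bars on it with a run-length thresholding rule, and derives
eleven quantitative traits. The mapping stage treats those traits (or any
phenotype) as the response in an F2 intercross and builds a multiple-QTL
model per trait: Haley–Knott regression scans on hidden-Markov genotype
probabilities, permutation significance thresholds, iterative cofactor
selection with backward elimination, Bayes credible intervals, and allelic
effects at peak markers. This vignette records the models, the parameters
that matter, the numerical choices, and what the built-in simulators do and
do not emulate.

# Profile extraction

A profile is the column-wise mean of a rectangular image region, one value
per pixel column, on the 0–255 gray scale (0 = black). The region is an
explicit input — the package does not attempt fish detection, rotation, or
landmark placement, which are manual steps upstream of this analysis. The
conventional region is 10 pixels high and spans the flank between the
opercle and the dorsal fin, but `extract_profile()` accepts any height
≥ 1. Color images are converted with the Rec. 601 luma weights
(0.299 R + 0.587 G + 0.114 B). Imaging pipelines differ in their RGB→gray
conversion, so exact parity with any specific tool's plotted profile is not
claimed; users who need a particular conversion can supply pre-grayscaled
images. Column means are kept in floating point — no rounding or
quantization is applied, since any fixed quantization would be an arbitrary
loss. Profiles are stored anterior→posterior; images of right-facing fish
should be extracted with `flip = TRUE`.

Standard length is the Euclidean distance between the snout and
caudal-peduncle landmarks times the image scale (cm/px).

# Bar calling

The segmentation threshold is the profile's own mean gray value, making
the rule scale- and illumination-shift invariant (adding a constant to all
pixels changes nothing). Scanning left to right in the interbar state:

- a **bar opens** at the first pixel of the first run of at least
  `min_run` consecutive values *strictly below* the mean;
- an open **bar closes** when a run of at least `min_run` consecutive
  values at or above the mean occurs; the bar's end is the last below-mean
  pixel before that closing run, so shorter bright interruptions remain
  inside the bar;
- a bar still open at the end of the profile closes at the last pixel;
- everything else, including leading and trailing stretches, is interbar.

Three tie/boundary conventions deserve note. Values exactly equal to the
mean count as interbar: the rule is "strictly darker than average", so a
constant profile has zero bars. The closing criterion is the complement of
the opening one (≥ mean rather than a separate "strictly above" rule), so
every pixel is classified and bars and interbars exactly partition the
profile. Leading and trailing segments count as interbars, consistent with
treating a nearly barless flank as one long interbar.

`min_run` defaults to 5 pixels. That default reflects empirical tuning on
real flank profiles at the image scales this kind of analysis uses
(~100–250 columns per flank); it is exposed as a parameter for sensitivity
analysis, and the test suite exercises other values against an independent
run-enumeration oracle.

# The eleven traits

Seven pigment-level traits (gray units, larger = lighter): darkest and
lightest intensity, their range, the sample covariance (n−1 denominator)
between 0-based pixel position and gray value, mean intensity over bar
pixels, mean intensity over interbar pixels, and the differential (interbar
minus bar, so positive = bars darker than their background). Four
patterning traits: number of bars, percent barring (bar pixels / profile
length), and mean bar and interbar widths converted to centimeters.

Two definitional choices were genuinely open. The position covariance is
implemented literally as `cov(position, intensity)`; an intuitive reading
of the trait as "bar/background discrepancy" would suggest the variance of
intensity instead, but the literal covariance is what the name says and is
what the package computes. Widths are residualized in centimeters rather
than pixels so that their units are commensurate with standard length;
because the conversion is linear, the choice only rescales the residuals.
Bar-dependent traits are *missing*, not zero, when a profile has no bars —
zero would conflate "no bars" with "maximally dark bars".

Residualization regresses each trait on standard length by OLS over a fit
population (by default all rows — parentals plus hybrids) and stores
observed-minus-predicted for every row. Residuals are exactly orthogonal
to standard length on the fit population and the operation is idempotent.
Group comparisons are one-way fixed-effects ANOVA with Tukey HSD post-hoc
pairs; the degenerate all-constant case is reported as F = 0, p = 1 rather
than NaN. Trait correlations are pairwise-complete Pearson r with
two-sided t-test p-values, computed on residualized values for
trait-versus-trait cells and on raw values against standard length itself
(residuals are orthogonal to length by construction, so correlating them
with length would be vacuous).

# Cross representation and genotype probabilities

A cross is a linkage map (linkage group, cM), an individuals × markers
genotype matrix coded AA/AB/BB/missing (A = granddam allele, B = grandsire
allele), and a phenotype table. The CSV dialect places marker linkage
groups and cM positions in rows 2–3 under the marker columns, with
genotype codes A/H/B/−.

Marker QC is the χ² test of observed genotype counts against the 1:2:1 F2
expectation with Bonferroni correction across markers; markers with
adjusted p < 0.05 are flagged as segregation-distorted. All-missing
markers are untestable and kept, with a warning.

Genotype probabilities come from a forward–backward pass over the hidden
genotypes {AA, AB, BB} per individual and linkage group: initial
distribution (¼, ½, ¼); transitions built from two independent gametes
each recombining with the Haldane probability r(d) = (1 − e^(−2d))/2
(d in Morgans, no crossover interference); emissions give 1 − ε to the
observed code with the error mass ε split evenly over the other two codes,
and are uninformative at missing genotypes and pseudomarkers. The Haldane
function was chosen because it is the standard no-interference map
function and because the package's own cross simulator uses the same
model, making the probabilities exact for simulated data. Defaults:
pseudomarker step 1 cM (finer than typical marker spacing at negligible
cost) and genotyping error rate 1e−4 (small but nonzero, so isolated
miscalls cannot force impossible paths). All linkage groups are treated as
autosomal; sex is metadata only.

# Scans, thresholds, and the multiple-QTL model

The Haley–Knott scan regresses the phenotype at each grid position on the
expected additive dosage p_BB − p_AA and the dominance indicator p_AB,
plus any cofactor columns, and reports
LOD = (n/2)·log10(RSS_null/RSS_full) against a null of intercept plus
cofactors. Haley–Knott regression (rather than EM interval mapping) was
chosen because the model-building procedure is regression-based anyway, it
is exact at fully typed markers, and it is fast enough to make 1000
permutations routine. Individuals with missing phenotype are dropped
(n is the complete-data count); positions within `drop_window` (default
10 cM) of a cofactor on the same group are scanned with that cofactor
removed from both models, so a cofactor cannot absorb its own signal.

Permutation thresholds shuffle the phenotype across individuals, keep
genotypes fixed, record the genome-wide maximum LOD per permutation, and
take empirical type-7 quantiles: 5% = significant, 10% = suggestive.
Internally all permutations are scanned as one multi-column regression per
position (the projection of a permuted response onto each position's design
reuses one QR decomposition), which is what makes the calibration
simulations below cheap.

Model building per trait: (1) an initial cofactor-free scan proposes
candidates — peaks above the suggestive cutoff on distinct linkage groups
or ≥ `min_sep` (default 30 cM) apart within one; (2) scans iterate with
the candidates as cofactors, each candidate's position refreshed by a
conditional scan (all others in the model, itself dropped) restricted to
the contiguous region not claimed by a same-group neighbour, and new peaks
clearing the suggestive cutoff are admitted, until stable (≤ 10
iterations); (3) backward elimination repeatedly removes the cofactor with
the lowest conditional LOD while that LOD is below the suggestive cutoff.
The admission and retention cutoff is the 10% threshold; published MQM
analyses rarely state their exact cutoffs, so this choice is explicit and
configurable rather than claimed canonical. The 30 cM separation exists to
prevent near-collinear cofactors. A model with zero QTL is a valid result.

Each surviving QTL is annotated from its conditional scan: peak position
and LOD; the Bayes credible interval (each grid position weighted by
10^LOD, normalized over the linkage group, smallest contiguous
peak-containing span with ≥ 95% of the mass — the contiguous form matches
conventional chromosome-interval reporting); PVE = 100·(1 − 10^(−2·LOD/n))
at the conditional peak, which doubles as the single-QTL heritability
column of the report; genotype class means and a = (m_BB − m_AA)/2,
d = m_AB − (m_AA + m_BB)/2 at the nearest true marker (observed genotypes
when available, most-probable imputed ones otherwise). The cumulative PVE
for a trait is the R² of the joint regression on all retained QTL, not the
sum of single-QTL PVEs, which would double-count correlated positions.

# The simulators

`simulate_profile()` paints rectangular bar/interbar blocks (optionally
jittered widths, linear background trend, Gaussian edge blur off by
default, iid pixel noise, clipped to [0, 255]) and returns the painted
segments as ground truth; edges are crisp by default precisely so ground
truth is unambiguous for segmentation tests.
`simulate_population_profiles()` emulates a two-parental-species-plus-F2
imaging study: by default the first parental cohort has the larger
bar/interbar contrast, sex is a 50/50 label with no phenotypic effect, and
standard length is lognormal with mean 4.1 cm (CV 0.15) — a plausible
scale for young-adult cichlids, not a fitted value, since parental trait
distributions are not numerically specified anywhere; these defaults are
illustrative.

`simulate_f2_cross()` draws each F2 individual as two independent gametes
from fully heterozygous F1 parents; along a linkage group a gamete is a
two-state Markov chain with Haldane switch probabilities (no
interference), which keeps simulator and HMM consistent. Phenotypes are
the sum of per-QTL effects (−a, d, +a for AA, AB, BB at the QTL locus,
which may sit between markers), an allometric term in standard length, and
Gaussian noise; genotypes are then masked to missing at a requested rate.

What the simulators do **not** emulate: xanthophore/iridophore color
channels, blotched (non-barred) morphs, dorsoventral bar structure,
two-grandsire pedigrees, segregation distortion, genotyping-error
clustering, or crossover interference. Tests passing on simulated data
therefore validate the algorithms and their calibration under the stated
model, not robustness to every artifact of real images or real
ddRADseq genotyping.

# Numerical choices and degenerate inputs

- LOD values are clamped at 0 against floating-point noise; RSS ratios
  use a 1e−300 floor before the log.
- Rank-deficient (collinear) design matrices are handled by projecting on
  the first `rank` columns of the QR decomposition.
- Forward and backward HMM passes are row-normalized at every step to
  avoid underflow on long linkage groups.
- Grid positions are rounded to 1e−6 cM when merging markers with the
  pseudomarker lattice; coincident markers multiply their emissions.
- Zero-variance phenotypes, empty profiles, coincident landmarks,
  out-of-range gray values, degenerate regressors (< 3 rows or constant
  standard length) and QTL on absent linkage groups are all rejected with
  informative errors; empty genotype classes and untestable markers
  produce missing values with warnings instead.
- Integer segment widths in the profile simulator are apportioned by
  largest remainder so painted widths always sum exactly to the profile
  length with every segment ≥ 1 px.

# Scales used by the test suite

The suite verifies segmentation against an independent run-enumeration
oracle on 1000 random profiles (lengths 30–400), trait identities on 500,
and scan LODs against a least-squares oracle on a fully typed 3 × 20-marker
cross (n = 200). Calibration checks use deliberately modest sizes chosen to
make the full suite a coffee-break run on one core: genome-wide type-I
error over 200 null crosses (n = 100, 3 groups × 30 markers at 10 cM,
200 permutations each), additive-QTL recovery and Bayes-interval coverage
over 100–200 replicates at n = 250 with a 20%-PVE planted QTL, and
underdominance recovery over 50 replicates. The permutation count in these
simulations (200) is smaller than the 1000 recommended for a real
analysis; thresholds at 200 permutations are noisier but unbiased, which
is acceptable when the quantity under test is an average over many
replicates.

# Known limitations

- The bar-calling rule conditions on the profile mean, so extreme
  vignetting or strong anterior-posterior lighting gradients shift the
  threshold; the simulator's `background_slope` exists to probe this.
- Haley–Knott LODs are approximations away from markers when genotypes
  are missing; with dense markers and low missingness the approximation
  error is negligible, but it grows with missing-data fraction.
- No epistasis (two-dimensional) scans, no X-specific thresholds, no
  composite interval mapping, and no candidate-gene annotation.
- The MQM admission/elimination cutoffs are a documented convention
  (suggestive threshold), not a universal standard; conclusions near the
  cutoff deserve a sensitivity check via the exposed parameters.
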