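---
title: "Elemental stoichiometry from MS1-only feature tables: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elemental stoichiometry from MS1-only feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms1stoich)
```

## The problem

Untargeted LC-HRMS of environmental extracts (the motivating case is soil
under contrasting land-management regimes) detects thousands of spectral
features, of which only a small fraction match any compound library. The
remainder - MSI level 4 features, known only by accurate mass and retention
time - still carry chemical information: a high-resolution mass constrains
the molecular formula, and a formula fixes the elemental composition. This
package turns a plain feature table (m/z, retention time, per-sample
intensities from a negative-mode `[M-H]-` acquisition) into:

1. candidate CHNOPS molecular formulas per feature,
2. a *composite formula* per feature (the average of its top candidates),
3. stoichiometric ratios C/N, C/P and N/P, and
4. group-level statistics: Kruskal-Wallis across groups, pairwise tests
   against a designated reference group with effect sizes, volcano-style
   significant-feature sets with UpSet-style intersection counts, and PLS-DA
   with VIP scores and k-fold Q2.

A seeded synthetic-data generator produces feature tables with known true
formulas and planted effects, so every stage of the pipeline is validated
against ground truth in the test suite.

## Formula assignment

### Mass model

All masses are neutral monoisotopic masses (1H 1.0078250319, 12C exactly 12,
14N 14.0030740052, 16O 15.9949146221, 31P 30.97376151, 32S 31.97207069 Da).
The deprotonated ion satisfies `m/z = M - 1.007276466`; the proton mass (not
the hydrogen-atom mass) is used so the electron is accounted for. The mass
tolerance is 2 ppm for neutral masses below 500 Da and 5 ppm at or above
500 Da - matching routine Orbitrap accuracy - with the 500 Da boundary
assigned to the looser regime.

### Enumeration

`enumerate_candidates()` is exhaustive within element bounds (defaults C 70,
H 120, N 20, O 30, P 8, S 8, chosen so enumeration at 1000 Da completes in
well under a second). It scans a precomputed N/O/P/S mass grid crossed with
the carbon count; the hydrogen count is then pinned by the ppm window, which
at these tolerances is far narrower than one hydrogen mass. A test verifies
set-equality against a naive six-element brute-force scan.

Candidates must pass:

* **element-ratio ranges** (H/C in [0.2, 3.1], N/C <= 1.3, O/C <= 1.2,
  P/C <= 0.3, S/C <= 0.8) - the widely used "common range" heuristics for
  organic molecules; all limits are configurable;
* **RDBE**: `C - H/2 + (N + P)/2 + 1` must be non-negative and
  integer-valued. Trivalent phosphorus is the default (a pentavalent switch
  exists); oxygen and sulfur are divalent. Integer RDBE is the valence
  requirement for an intact neutral molecule; the equivalent nitrogen-rule
  parity is also reported per candidate but never used to reject, because
  electron bookkeeping for deprotonated ions is ambiguous;
* **isotope match score >= 30%** (next section).

An empty candidate set is a valid outcome: the feature stays unassigned.

### Isotope patterns and the match score

Theoretical A+1..A+3 abundances are computed by exact truncated polynomial
convolution of the per-element natural isotope distributions (13C 1.07%,
34S 4.25%, 18O 0.205%, ...), expressed as percent of the monoisotopic peak.

When no measured isotope abundances accompany the table - the normal
situation for the MS1-only workflow this package supports - scoring uses a
conservative placeholder observation of 5% for each of A+1, A+2 and A+3
with a 5% abundance error. The score is defined as

```
score = 100 * mean_k max(0, 1 - |obs_k - theo_k| / (max(obs_k, theo_k) + err))
```

over the three peaks. It is 100 exactly when the patterns agree, decreases
monotonically in each absolute deviation, and the additive error term keeps
it tolerant where either abundance is small. The denominator was chosen
deliberately: with the placeholder observation, any scoring rule that
normalises by `max(obs, theo, err)` alone would reject most formulas with
more than ~8 carbons (their A+1 exceeds 8%, far from the 5% placeholder),
which would defeat the purpose of a placeholder that is meant to let
plausible formulas through while removing only gross mismatches. A test
verifies that realistic formulas up to 900 Da all clear the 30% cutoff under
placeholder scoring.

### Ranking

Up to three candidates are retained per feature, ordered by absolute mass
error (ppm) first, isotope match score second, and the Hill-order formula
string as a deterministic tiebreak. Mass error ranks first because it is the
only observation-driven evidence in this setting: under placeholder isotope
scoring the score is a function of the candidate alone and systematically
prefers compositions whose pattern happens to sit near 5/5/5, regardless of
the observed feature. With mass-error-first ranking, the true formula of
synthetic features (mass < 500 Da, 0.5 ppm error SD) lands in the top 3 for
94-98% of features across seeds, versus ~84% under score-first ranking.

## Composite formulas and ratios

The top candidates (1-3) are averaged with equal weights into a composite
formula. Two averaging modes are shipped because "average the ratios of the
top candidates" genuinely admits two readings:

* `average-counts` (default): average the element counts, then form ratios
  of the mean counts. This is the reading under which the averaged object
  itself is a (rational) formula.
* `average-ratios`: form each candidate's ratio, then average the defined
  ratios.

The modes coincide whenever candidates share the denominator element count
(verified as a property over random candidate triples); reports name the
mode used. A ratio is undefined exactly when its denominator mean count is
zero; undefined ratios are excluded per ratio rather than imputed, so a
nitrogen-free feature still contributes to C/P.

`ratio_outlier_trim()` implements the 1.5 x IQR trim (type-7 quartiles) used
only for distribution plots; statistics always run on the complete data.

## QA/QC gates

* **Blank retention**: a feature is kept iff its mean non-blank intensity is
  *strictly* greater than 3x its blank signal. The blank signal is the mean
  across blanks by default (max by configuration), and strictness is the
  conservative reading of an "at least >3x" rule. Features absent from
  blanks are kept whenever they carry any sample signal - the rule is
  formulated without division so 0/0 never arises. The filter is idempotent.
* **Internal standards**: CV (%) of spiked standards across non-blank
  samples, with a configurable acceptance threshold (default 30%).
* **Mass normalisation**: per-sample division by sample mass (mg), used for
  the identified-metabolite workflow (mass -> log -> Pareto).
* **Injection-order drift**: a report-only regression of log IS intensity on
  injection order. No drift or batch correction is applied - small studies
  (< 30 samples) do not support the usual correction methods, so the
  diagnostic is informative only.

## Preprocessing and group statistics

Unknown-feature matrices follow the fixed order quantile normalisation
(delegated to `limma::normalizeQuantiles`, ties averaged) -> IQR filter
(dropping the least-variable 25% by default) -> log -> Pareto scaling
(`(log x - mean) / sqrt(sd)`); identified-metabolite matrices follow mass
normalisation -> log -> Pareto. The log offset is half the smallest positive
value in the matrix; zero-variance features are centred and flagged. After
Pareto scaling each feature's variance equals the standard deviation of its
logged values - an identity the tests check to 1e-10.

Ratio-level inference treats the feature as the observational unit. Each
feature's composite ratios are attributed to the groups where the feature is
abundant: it counts toward group g when its mean intensity in g is at least
half its maximum group mean (configurable). This presence rule converts one
feature table into per-group ratio distributions; it is an artifact
definition, made explicit because intensity-weighted and detection-based
alternatives exist and field practice is not standardised.

Group comparisons use the Kruskal-Wallis rank test (tie-corrected H,
chi-square p; an exhaustive-permutation p is available for n <= 10) followed
by pairwise two-sided Mann-Whitney tests against the reference group only.
Effect sizes are Cohen's d (pooled SD, positive when the comparison group
exceeds the reference) labelled negligible/small/medium/large at 0.2/0.5/0.8,
with the rank-based Cliff's delta co-reported because d on skewed ratio
distributions is fragile. Ratio-level pairwise p-values are reported
unadjusted (five planned contrasts against one reference); feature-level
volcano tests default to Benjamini-Hochberg.

Volcano-style significant-feature sets use a Welch t-test on log intensities
(the package's choice; fold-change-plus-t is the standard volcano
construction) with gates p < 0.05 after BH and |log2 FC| >= 1, both
configurable and recorded in reports. Exclusive intersection counts over the
per-group sets (`upset_counts()`) partition the union, as UpSet plots
display.

## PLS-DA

`plsda_fit()` is a NIPALS PLS2 regression of the column-centred one-hot
class matrix on the centred data matrix. Determinism is guaranteed by a
fixed start (the largest-variance Y column) and a sign convention (each
component's largest-magnitude weight is positive). VIP scores use the
standard formula; their mean square is exactly 1, and variables with VIP > 1
are flagged as discriminating. `cross_validate()` reports R2 from the full
fit and Q2 = 1 - PRESS/TSS with PRESS pooled over seeded stratified k-fold
held-out predictions of the one-hot matrix and TSS taken about the overall
class means - one of several Q2 conventions, hence stated explicitly. With
four samples per class and five folds, stratification degrades gracefully:
each class simply appears in a subset of folds. The implementation is
cross-checked in the tests against mixOmics (scores to |r| > 0.999, VIPs to
1%).

Q2 on data with a between/within variance ratio of 9 exceeds 0.99 at
synthetic scale, and label permutation drives it negative - the package
reproduces the qualitative behaviour expected of a sound PLS-DA validation,
but numeric R2/Q2 values from any real study depend on the underlying raw
data and are not reproducible from summaries.

## The synthetic-data generator

The generator is first-class, tested code; it emulates:

* `[M-H]-` m/z values with Gaussian ppm error truncated at +/-3 sigma
  (default SD 0.5 ppm, inside a +/-5 ppm instrument envelope), exactly
  reconstructible from the stored truth;
* retention times respecting dual scan windows (m/z 85-800 before 9 min,
  110-1000 after);
* log-normal intensities around per-feature baselines (baseline meanlog
  log(1e6), SD 1) with per-group log2 effects and within-group noise of
  0.3 log units - pooled, homogenised aliquots put this study design at the
  technical-replicate end of variation, which 0.3 represents; it is a free
  parameter of the generator, documented rather than asserted;
* water blanks: 20% of features appear in blanks at 1/10 of their median
  level (retained by the 3x rule) and 5% are pure background with blank
  signal comparable to sample signal (removed by it), so the rule is
  exercised in both directions;
* two spiked internal standards (phenylalanine- and tryptophan-like
  formulas) in all non-blank samples at a target CV of 5%, bracketing the
  low single-digit CVs a stable run produces;
* stoichiometric group contrasts, planted compositionally: the reference
  group's formula library is enriched in phosphorus (60% of formulas
  P-bearing with 1 + Binomial(3, 0.6) atoms, versus 30% and 1 +
  Binomial(3, 0.05) elsewhere), which lowers its C/P and N/P without
  dictating intensities. The magnitude is a free parameter chosen to plant a
  clearly "moderate to large" contrast (realised |d| ~ 0.9-1.5).

What the generator does *not* emulate: chromatographic peak shape, adducts
other than `[M-H]-`, in-source fragments, correlated features from shared
pathways, missing values, retention-time drift or batch structure.
Consequently, passing tests demonstrate the correctness and calibration of
the pipeline's computations, not robustness to every artefact of real
acquisitions.

## Numerical and scale choices

* Enumeration windows are exact in ppm relative to the theoretical m/z; the
  brute-force equivalence test uses reduced element bounds (C 18, H 36, N 8,
  O 12, P 3, S 3) so the naive scan stays tractable.
* The exhaustive Kruskal-Wallis permutation null is limited to n <= 10. At
  n = 8 the chi-square p agrees with the exhaustive p to within 0.05 for
  contiguous two-group splits with both groups >= 2; for singleton groups
  the discrete null (8 permutations) makes agreement with any continuous
  approximation impossible, which is a property of the approximation, not of
  the implementation.
* Test and validation cohorts use 200-300 features and 4 samples per group -
  the package's chosen synthetic scale, mirroring a small field study while
  keeping the full suite under a minute.
* All randomness flows through explicit integer seeds; identical
  configuration and seed reproduce report bundles byte for byte, and every
  output table carries a config hash and the seed in a header comment.

## Known limitations

* CHNOPS only; no halogens, silicon or metal adducts, and no adducts beyond
  `[M-H]-`. Features ionising otherwise will be mis-assigned or unassigned.
* Placeholder isotope scoring cannot distinguish candidates by isotopes; it
  only removes gross mismatches. Supplying measured A+1..A+3 abundances
  makes the score informative, and the ranking then benefits from it as a
  secondary key.
* Composite formulas are averages over candidates, not identifications;
  ratios inherit candidate uncertainty and should be read as ensemble
  stoichiometry.
* The presence rule for per-group ratio distributions is a pragmatic
  definition; conclusions should be checked against its threshold.
* No drift/batch correction, by design, for small randomised runs.
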