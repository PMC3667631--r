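---
title: "Two-stage hit calling for plate-based RNAi secretion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hit calling for plate-based RNAi secretion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucinscreen)
```

## The problem

Genome-scale siRNA screens read out one number per well — here, the
chemiluminescence of secreted mucin (MUC5AC) captured from a 96-well
plate after stimulating secretion with PMA. Two statistical obstacles
stand between those raw numbers and a hit list:

1. **Spatial and plate artifacts.** Liquid handling, incubator position
   and detection produce systematic row, column and whole-plate biases
   that easily exceed true knockdown effects.
2. **Low replication.** Each gene is measured in triplicate, one well per
   replicate plate set, so per-gene inference must lean on robust
   statistics rather than well-powered tests.

`mucinscreen` implements the canonical two-stage answer: a primary screen
normalized per plate with **B-scores** and thresholded on the **median
B-score** at ±1.5, with **rank-product** statistics carried as
consistency annotations, followed by a validation screen normalized with
plate-wise **z-scores** and called against a **mock ± 2 SD** band. It
also ships a synthetic screen generator with ground truth, because the
original raw plate data of the screen that motivated this design were
never deposited — every statistical claim in this package is established
on simulated screens whose truth is known.

## The model behind the B-score

A plate of signals \(x_{ij}\) is decomposed by Tukey's two-way median
polish into

\[ x_{ij} = \mu + r_i + c_j + \varepsilon_{ij}, \]

with overall level \(\mu\), row effects \(r_i\), column effects \(c_j\)
(both with median zero) and residuals \(\varepsilon_{ij}\). The B-score
of a well is its residual scaled by the plate's robust spread:

\[ B_{ij} = \frac{\varepsilon_{ij}}{1.4826 \cdot
   \operatorname{median}\left(\lvert\varepsilon\rvert_{\text{sample
   wells}}\right)}. \]

Medians make the fit indifferent to a minority of true hits; the MAD
(with the Gaussian-consistency constant 1.4826) makes scores comparable
across plates. Assumptions worth stating: artifacts are additive row +
column surfaces on the scale being polished, the majority of wells on a
plate are phenotypically null, and hits are a minority in every row and
column.

Two conventions the upstream literature leaves open, fixed here and
flagged as conventions, not reconstructions:

* **Control wells enter the polish but not the MAD.** Controls sit in
  fixed wells, so excluding them would leave their rows and columns
  under-determined; but they sit at extreme levels *by design*
  (especially the unstimulated −PMA wells) and would inflate a MAD they
  entered.
* **Controls receive B-scores** for diagnostics, flagged as non-gene
  wells and never ranked.

## Numerical choices

**Canonical initialisation.** The median-polish fixed point is not
unique: on even-sized grids (midpoint-of-pair medians) distinct additive
surfaces can leave every row and column residual median at zero, and
which fixed point the raw iteration reaches depends on the starting
matrix. In practice this breaks a property one should demand of any plate
normalization — that adding a row offset, a column offset, a plate offset
or rescaling the plate leaves B-scores untouched. We observed converged
decompositions of the same plate differing by ~1e−2 in their residuals
after such transformations. `median_polish()` therefore starts with a
single least-squares sweep (column means, then row means), which is
*exactly* equivariant under those transformations, and refines with pure
alternating median sweeps. Every contract of the decomposition —
reconstruction identity, zero-median effects, NA-awareness — is
unchanged; on odd-sized grids, where the fixed point is unique, the
result coincides with `stats::medpolish` to machine precision (this is
cross-checked in the test suite). `init = "none"` restores the textbook
iteration.

**Convergence.** Sweeps stop when no effect moves more than `tol`
(default 1e−6 signal units) or after `max_iter = 100` sweeps. Median
polish can cycle; hitting the cap is a warning, not an error, which is
the accepted practice.

**Degenerate plates.** `median_polish()` refuses any row or column with
fewer than two observations. `b_score_plate()` is the pragmatic layer
above it: rows/columns with fewer than two measured wells (the partly
filled final plate of a screen) are trimmed before fitting and their
wells receive `NA` B-scores with a warning; the plate as a whole is
degenerate only if less than a 2×2 grid survives or the sample-well MAD
is zero. A zero MAD signals a constant or exactly additive plate — on
such a plate B-scores are undefined, and a screen simulated without
noise fails loudly on every plate rather than silently producing zeros.

**Ties** inside medians use the standard midpoint-of-order-statistics
convention; ranks use average ties, which preserves rank-sum totals.

**Calibration caveat.** B-scores on a 96-well plate are *not* exactly
standard normal under pure noise. The polish spends 21 median parameters
on 96 cells, so residuals carry excess mass near zero and the MAD
underestimates the residual SD; the per-plate SD of null B-scores is
typically ~1.3 (and ranges up to ~1.7). This is a property of the
B-score construction at this plate size, not of this implementation —
`stats::medpolish` residuals behave identically. Consequences: the ±1.5
cut is in practice more permissive than "1.5 robust SDs", and all
calibration statements in the tests are made against the *empirical*
null B-score distribution rather than N(0,1). The null-screen test
verifies exactly that: the observed ±1.5 hit rate of the median-of-3
statistic matches the binomial expectation implied by the empirical
per-replicate tail mass.

## Rank products

Within each replicate, genes are ranked by B-score ascending (rank 1 =
strongest hyposecretory candidate) and descending (hypersecretory); a
gene's rank product is the geometric mean of its K ranks. Significance
uses a permutation null that redraws K uniform rank permutations per
round and recomputes all rank products; the p-value uses the add-one
convention \(p = (c + 1)/(Bn + 1)\) so the best attainable statistic
never reports exactly zero, and the expected false-positive proportion is
\(\mathrm{pfp} = p \cdot n / \mathrm{rank}\). Two one-tailed analyses are
reported rather than one two-tailed statistic because the screen
classifies hits by direction.

A deliberate scope decision: **rank products annotate, they do not
gate**. The primary hit call is the median B-score against ±1.5,
strictly (`|median| > 1.5`; a median of exactly ±1.5 is not a hit, so
boundary behaviour is deterministic). The rank-product columns travel
with the hit table as a replicate-consistency measure; no p or pfp
cutoff is applied anywhere in the default pipeline, and no further
multiple-testing correction is layered on top of pfp.

## The validation stage

Validation re-screens the filtered hits with an independent siRNA set —
in silico, with a fresh layout and fresh noise. Signals are normalized
plate-wise as \(z = (x_i - \overline{x_n})/\mathrm{SD}(x_n)\) with the
sample SD, where \(x_n\) is read as *all measured wells of the plate*
(samples and mocks together). A gene is validated when its mean z across
replicates falls outside \(\bar z_{\text{mock}} \pm 2\,
\mathrm{SD}(z_{\text{mock}})\), the band being computed on the z scale
from the stimulated (+PMA) mock wells. Choices made where the upstream
description is ambiguous: the band is on z-scores, not raw
chemiluminescence (the formula is plate-wise, and the cutoff references
mock samples after normalization); replicates are aggregated by the
mean, not the median (z-normalization already tempers outliers, and
three values give medians little to work with).

Between the stages sit two triage filters. `filter_by_annotation()`
removes hits whose user-supplied categories (e.g. secreted, nuclear,
basic metabolism) intersect a blocklist, case-insensitively, any-match;
unannotated genes are retained and flagged — the package does not ship
or emulate any annotation database. `expression_filter()` keeps genes
whose expression relative to a housekeeping control exceeds a detection
floor (default 0.05 relative units, deliberately exposed as
configuration since no principled universal floor exists) and labels
starved-vs-nonstarved regulation with a two-sided Welch test at α = 0.05
— the unequal-variance default is the safe choice at n = 3 with no
stated test.

## What the generator emulates — and what it does not

`simulate_screen()` produces the statistical structure the analysis
assumes it must remove or resist:

| parameter | default | meaning |
|---|---|---|
| `baseline_signal` | 1000 AU | stimulated (+PMA) mock level |
| `minus_pma_fraction` | 0.25 | unstimulated level as fraction of baseline |
| `plate_effect_sd` | 0.1 | log-scale SD of whole-plate multiplier |
| `row_effect_sd`, `col_effect_sd` | 0.05 | log-scale SD of row/column gradients |
| `noise_cv` | 0.1 | CV of per-well lognormal noise (mean 1) |
| `hypo_fraction`, `hyper_fraction` | 0.05, 0.02 | spiked hit fractions |
| `hypo_effect`, `hyper_effect` | 0.25×, 2.5× | spiked effect multipliers |

A well's signal is `baseline × plate × exp(row + col) × gene × noise`.
Noise is multiplicative lognormal because luminescence is positive and
right-skewed, and ratios of signals must stay well defined. Defaults are
the package's single statement of a "realistic screen": ~10 % well-level
CV and hit effects of 4× in either direction are typical of
chemiluminescent secretion assays with effective knockdowns; they are
fixed once here and are not tuned against test outcomes. Layout is a
pure function of the design — genes fill plates in well order (controls
fixed in the last column, +PMA mocks on top), identically across
replicates, so plate position and gene index are deliberately
confounded and only the normalization can untangle them. Signals for
every (replicate, plate) come from a deterministic substream of the one
design seed: the same seed reproduces tables bit for bit, and a new seed
moves signals but never wells.

Not modelled, by decision: transfection-efficiency variation, cell-death
off-target artifacts, optical crosstalk between wells, edge-specific
evaporation effects beyond the generic row/column gradients. A green
test therefore establishes that the pipeline recovers truth *under the
stated artifact model*; it cannot certify behaviour under artifact
classes the generator does not produce.

## What the tests establish

* Median polish equals an independently coded brute-force oracle on
  ≥100 random matrices (≤1e−9), with the reconstruction identity exact.
* B-scores are invariant (≤1e−9) to simultaneous row/column/plate
  offsets and positive plate scaling on 50 random plates.
* Rank products match closed forms; for K = 1 the permutation p-value
  converges to the exhaustive rank/n answer (±0.02).
* On a no-hit screen with all artifacts on, rank-product p-values are
  uniform (KS < 0.05) and the ±1.5 hit rate matches the empirical
  tail-mass expectation within a 3σ binomial band.
* Strong hypo spikes (0.25×, 5 % of 2000 genes) are recovered by the
  two-stage pipeline with sensitivity ≥ 0.9, and validation strictly
  reduces the false-positive count (in the frozen regression run: 113
  stage-1 false positives, 0 after stage 2, all 140 spiked hits kept).
* Identical config + seed ⇒ byte-identical outputs; every CSV dialect
  round-trips losslessly (numerics written at 17 significant digits).

## Known limitations

* The published screen's headline hit counts cannot be reproduced — its
  raw plate data are not publicly available — so nothing here claims
  numerical agreement with that screen; the package reproduces the
  *procedure*, validated on synthetic ground truth.
* B-score miscalibration at 96-well geometry (above) means ±1.5 is an
  operational cutoff, not a false-positive-rate statement.
* The permutation null assumes exchangeable ranks across genes within a
  replicate; correlated plate-level failures that survive B-scoring
  would violate it.
* `quantify_intensities()` treats intensities as given numbers: no image
  densitometry, and qPCR values are assumed already
  efficiency-normalized.
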