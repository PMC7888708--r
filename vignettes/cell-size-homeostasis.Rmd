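---
title: "Quantifying cell-size homeostasis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-size homeostasis: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsizer)
```

## The problem

Rod-shaped cells such as fission yeast grow by linear tip extension and
divide at a remarkably uniform length (around 13–14 µm), implying a
homeostatic mechanism that senses size and advances or delays mitosis to
correct deviations. Two complementary quantitative readouts probe this
mechanism in single-cell data:

* **Dispersion of size at division.** The coefficient of variation
  (CV = 100·SD/mean) of cell length at division measures how precisely the
  population converges on its target size. Gene deletions that inflate the
  CV are candidates for components of the size-sensing machinery. Because
  the CV is sensitive to a handful of abnormally long cells, the quartile
  coefficient of variation (CQV = 100·(Q3−Q1)/(Q3+Q1)) is reported
  alongside it as an outlier-robust companion.
* **The BL/E plot.** Plotting each cell's length extension during one cycle
  (E = division length − birth length) against its birth length (BL)
  reveals the control mode. Perfect size sensing ("sizer") gives a slope of
  −1: a cell born large extends correspondingly less. Adding a fixed
  increment per cycle ("adder") gives slope 0; a pure clock ("timer") gives
  slope 0 under linear growth and +1 under exponential growth at
  rT = ln 2. Wild-type fission yeast sits around −0.7 to −0.8, i.e. most of
  a size deviation is corrected within one cycle.

`cellsizer` implements both readouts, the statistical machinery around them
(an asymptotic test for CV equality, a skewness gate, a sample-size rule),
a screening pipeline that combines them, quantification of nuclear-division
synchrony in cytokinesis-blocked multinucleate cells, and a stochastic
lineage simulator that generates realistic inputs for all of the above.

## The lineage simulator

`simulateLineages()` grows each cell deterministically between divisions —
linear, `L(t) = BL + v·t`, by default, since fission yeast extends
linearly; exponential growth is available mainly to expose the timer's
positive BL/E slope — and divides it when its control trigger fires:

| control | trigger | noise |
|---------|---------|-------|
| sizer | length reaches `L_T + ε` | `ε ~ N(0, σ_T)`, µm |
| adder | length reaches `BL + Δ + ε` | `ε ~ N(0, σ_T)`, µm |
| timer | age reaches `T_dur + ε` | `ε ~ N(0, σ_T)`, min |

Each daughter receives a fraction `f ~ N(0.5, σ_f)` of the division
length, clipped to [0.3, 0.7]: division in these cells is near-symmetric,
and the clip prevents degenerate daughters under extreme draws. Cells
whose trigger is already satisfied at birth divide after one frame
interval (one minute when frame sampling is off) and are flagged rather
than dropped, so no zero cycle times arise.

**Time-lapse recording.** With `frame_interval = Δt > 0` (default 10 min,
matching typical microfluidic imaging), recorded birth length is the true
length at the *first frame at or after* the actual birth, recorded
division length the true length at the *last frame at or before* the
actual division, and cycle time is the frame-time difference. This
reproduces the convention of measuring birth at the first frame in which
two separate daughters are visible, and quantizes the recorded cycle time
downward by at most two frames. Independent `N(0, σ_m)` measurement noise
can be added to each recorded length. Extension is always computed as the
exact difference of the recorded lengths, so `E = D − BL` holds to the
bit.

**Defaults and presets.** The wild-type-like preset (`sizerPreset()`) uses
`L_T = 14` µm, `σ_T = 1.12` µm and `v = 0.0467` µm/min, giving a
division-length CV of 8% and a ~140-min cycle at the 7 µm birth length —
the regime of time-lapse measurements of wild-type cells. The mutant-like
preset (`adderPreset()`) adds `Δ = 7` µm with `σ_T = 1.94` µm; at
stationarity the adder's division-length SD is `σ_T·√(4/3)` (birth noise
is half the division noise and variances add), so this calibrates to a CV
of ~16%, i.e. a doubled CV with no change of mean — the phenotype the
screen is designed to catch. The daughter-fraction SD `σ_f = 0.02` keeps
division near-symmetric; founder distributions are centred on the
stationary birth length with the stationary birth SD so that even
three-generation runs are near steady state. `max_generations = 3`
mirrors the practice of only measuring the first three generations of a
time-lapse experiment. A single integer seed drives every draw in a run;
identical seed and parameters give bit-identical output, and the
simulator restores the caller's RNG state.

**What the generator does and does not emulate.** It produces steady-state
populations with realistic birth/division correlations, frame quantization
and measurement noise — the features the downstream statistics actually
consume. It does not model cell width or septum geometry, growth-phase
changes within a cycle (the bilinear pattern of real fission yeast),
lineage-correlated noise, phototoxicity drift, or septated-but-unseparated
regrowth artefacts. Tests passing on simulated data therefore validate the
statistical machinery and its calibration, not the biology of any
particular mutant.

## Dispersion statistics and the CV-equality test

All dispersion measures use fixed, documented conventions so values are
bit-stable: the sample SD (n−1), quartiles by linear interpolation of
order statistics (`h = (n−1)p + 1`, R's type 7), and skewness as the plain
moment ratio `g1 = m3/m2^{3/2}` with 1/n moments. At the n ≥ 50 sample
sizes the screen requires, the difference between g1 and its adjusted
variants is far smaller than the ±1 gate width.

`cvEqualityTest()` implements the Feltz–Miller asymptotic test: with
per-group CVs `c_i` and weights `m_i = n_i − 1`,

```
D_AD = Σ m_i (c_i − c̄)² / [c̄² (0.5 + c̄²)],   c̄ = Σ m_i c_i / Σ m_i,
```

referred to a χ² distribution with k−1 degrees of freedom. The statistic
is exactly invariant to rescaling any single group. P-values are reported
as computed, never truncated to zero. `cvEqualityPermutation()` provides
an independent reference: groups are scaled to mean 1, labels permuted,
and the statistic recomputed, with the add-one p-value `(b+1)/(B+1)`. The
test suite checks that the two routes give concordant p-values (Spearman
rank correlation above 0.9 over random two-group instances), that the
asymptotic test holds its nominal type-I error at n = 50 per group, and
that it detects a doubled CV (16% vs 8%, n = 50) with high power at
α = 0.001.

**Sample-size rule.** `sdCIFactors(n, conf)` gives the multiplicative
chi-square CI bounds for a normal SD, and `minSampleSizeSD(r, conf)`
returns the smallest n whose CI stays within a relative half-width `r`
of the estimate. Under this criterion r = 0.5 gives n = 18 (the upper,
chi-square-lower-tail bound dominates). Common lab practice of measuring
at least 50 cells is therefore more conservative than the formal
criterion; both `r` and the confidence level are exposed rather than
hard-coding any particular rule.

## The screen

`screenSelect()` applies four gates to a candidate strain against a
control: sample size (default min 50), CV direction (candidate above
control), CV significance (Feltz–Miller p < 0.001), and a skewness gate
(g1 within [−1, +1]). The skewness gate exists because partial activation
of a cell-cycle checkpoint produces a tail of arrested, elongated cells:
that inflates the CV for reasons unrelated to size sensing and skews the
length distribution towards larger cells. The significance test is kept
two-sided and the direction enforced as a separate gate — the p-value is
never halved — so the reported p is the familiar two-sided quantity. No
multiplicity correction is applied across candidates; the stringent
α = 0.001 gate plays that role in practice, and the false-positive rate of
the full decision rule is verified by simulation in the test suite. An
undersized candidate fails the n gate with `selected = FALSE` rather than
raising an error, since a screening table should report, not abort.
Whether mutants are compared pairwise against the control (the default,
via `screenStrains()`) or jointly is left to the user — `cvEqualityTest()`
accepts k groups.

## The BL/E analysis

`fitBLE()` regresses E on BL by ordinary least squares over the **raw**
records; the 0.5 µm birth-length cohorts (`cohortByBirthLength()`) are a
display device only, with half-open bins `[k·w, (k+1)·w)` anchored at 0 so
binning is reproducible regardless of the observed range. Records with
negative extension (possible under measurement noise) are retained and
counted — removing them would censor the noise distribution
asymmetrically and bias the slope. No errors-in-variables correction is
applied, matching standard practice in the field; the consequence,
documented and tested, is that measurement noise on BL biases the fitted
slope toward −1 (the same noisy BL enters E with opposite sign), so noisy
adder data can masquerade as partial sizer control.

`classifyControlMode()` maps the slope to a label with configurable
thresholds, by default: ≤ −0.6 `sizer_like`; (−0.6, −0.2] `impaired`;
(−0.2, +0.2) `adder_like`; ≥ +0.2 `timer_like`. The cut-points are
pragmatic conventions chosen so that slopes around −0.7 (wild type),
−0.46 (a partially impaired mutant) and −0.066 (homeostasis effectively
lost) land in distinct classes; they are parameters, not claims.

## Multinucleate synchrony and per-nucleus intensities

In cytokinesis-blocked cells the nuclei share one cytoplasm and normally
divide synchronously, so nuclei counts walk the series 2, 4, 8. Counts of
3, 5, 6 or 7 mark asynchronous divisions. `asynchronyFraction()` reports
the percentage of such cells **among cells with two or more nuclei**:
single-nucleus cells cannot yet have divided asynchronously and are
excluded from the denominator; when no cell has ≥ 2 nuclei the fraction is
undefined and returned as missing, never as 0. This denominator convention
is fixed, not configurable. Counts above 8 are binned as "8+" for display
while kept exact internally. Pooling across timepoints is the default
(concatenate the counts); per-timepoint summaries are obtained by calling
the function per timepoint.

`simulateMultinucleate()` provides the matching generator: synchronous
doubling, or independent per-nucleus division with probability q — a
branching process whose exact distribution is enumerable and serves as the
oracle in tests (e.g. at q = 0.5 after two cycles, P(4 nuclei) = q·q²).

`perCellIntensityCV()` quantifies uncoordinated accumulation of a nuclear
marker: the CV of per-nucleus intensities within each cell (sample SD over
the nuclei — typically only 4 — divided by the cell mean), plus the group
mean of per-cell CVs. The per-cell CV is exactly invariant to rescaling a
cell's intensities, so exposure differences between cells cancel.
Non-positive intensities are floored at a small positive value and
flagged.

## Numerical choices and degenerate inputs

* Quantile rule type 7 and n−1 SDs throughout (see above); these choices
  make every hand-checked example in the test suite bit-stable.
* `cvEqualityTest()` refuses a pooled CV of zero (all groups constant) and
  requires positive means and n ≥ 2 per group.
* `fitBLE()` errors on fewer than 3 records or zero birth-length variance
  and warns below 10 distinct birth lengths.
* Founder lengths are resampled until positive; daughter fractions are
  clipped (the clip count is reported in the run manifest).
* The pipeline writes a manifest with seed, version, parameter echo and
  flagged-record counts, and contains no timestamps, so a fixed
  (config, seed) pair reproduces every output byte-for-byte.

## Problem sizes used in the tests

The test suite and acceptance script run entirely on simulated data:
900-cycle lineage runs for slope recovery and CV calibration, 2000
replicates for the type-I and power checks of the CV test, 50 instances ×
999 permutations for the asymptotic-vs-permutation concordance, 1000
replicate screens for false-positive control, and 10⁴–10⁵ cells for the
branching-process comparisons. These sizes put Monte-Carlo error well
inside each assertion's tolerance while keeping the whole suite fast.

## Known limitations

* The simulator's growth is strictly mono-phasic and noise-free within a
  cycle; only trigger, partition and measurement noise are modelled.
* The asymptotic CV test assumes approximately normal underlying data; for
  heavy-tailed data the permutation variant is the safer choice.
* The BL/E slope is attenuated or inflated by measurement noise (no
  errors-in-variables correction), as documented above.
* Classification thresholds are conventions; near a boundary the label
  should be read together with the slope and its standard error.
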