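---
title: "Methods: reliability and reproducibility of individual-level functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability and reproducibility of individual-level functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Functional connectivity — the temporal correlation between the BOLD series
of two brain regions — is a candidate individual-level biomarker, but only
if a single subject's connectivity estimates are *reliable* (they rank
individuals consistently across repeated scans) and *reproducible* (two
acquisitions give similar values).  `fcrel` implements the full analysis
chain needed to quantify both as a function of scan duration and
data-removal strategy, plus a synthetic cohort generator with known ground
truth so every stage can be validated by parameter recovery rather than by
eyeballing.

The pipeline stages are:

1. **Parcellation** — greedy sphere packing of a gray-matter mask into
   ~5-mm regions, nearest-center voxel labelling, erosion of WM/CSF masks,
   mapping of literature MNI coordinates onto region labels, and
   ROI-average series extraction.
2. **Preprocessing** — discard of initial volumes, linear detrend, ideal
   Fourier bandpass (0.001–0.1 Hz), and regression of WM, CSF and 12
   motion parameters, each covariate filtered identically first.
3. **Connectivity** — pairwise Pearson correlation, Fisher z-transformed
   (`z = atanh(r)`), stored as a long tensor indexed by connection,
   subject, condition and run; paired task-vs-rest contrasts with
   Benjamini–Hochberg FDR control.
4. **Reliability** — per-connection ICC across subjects and repeated runs;
   per-region reliability maps against a strategic target subset; the
   ICC-versus-region-volume relation.
5. **Reproducibility** — per-connection RMS difference between repeated
   acquisitions, its scaling with scan duration, similarity matrices of
   group-mean connectomes, and the cross-subject correlation of
   connectivity between two conditions.
6. **Data removal** — simulated scrubbing (random volume deletion) versus
   truncation at matched fractions, re-running the chain and comparing
   mean ICC.

# The generative model

`simulate_run()` realises one acquisition in five steps.

**Target correlation.** The instantaneous correlation target is

    C(t) = tanh( group_z + subject_dev + task_delta + state(t) * state_sd * W )

where `group_z` is the true group-mean Fisher-z connectome, `subject_dev`
a stable subject-specific deviation, `task_delta` a condition-specific
shift confined to connections between task-engaged regions, `state(t)` a
unit-variance Ornstein–Uhlenbeck process with a minutes-scale correlation
time, and `W` a fixed random symmetric direction matrix.  The slow state
is the mechanism that makes *when* you sample matter: truncating a run
narrows the window of states sampled, while random scrubbing does not.

**Group connectome construction.** A tempting construction — drawing
every off-diagonal `group_z` entry i.i.d. normal with SD ~0.3 — does not
describe any realisable correlation matrix once the parcellation has more
than a handful of regions: the spectrum of such a matrix spreads like a
Wigner semicircle of radius `2 * sd * sqrt(n_rois)`, so at 50 regions the
smallest eigenvalue sits near −2.  Repairing that much negativity
distorts the connectome far from its nominal pattern.  Real connectomes
avoid this because they are low-rank-structured (regions organise into
networks).  The generator therefore builds the group connectome as
`cov2cor(L L' + s2 * I)` from network loadings `L` (each region loads on
one of up to six networks, with weak cross-loadings) and calibrates the
idiosyncratic variance `s2` by root finding so that the SD of off-diagonal
Fisher-z entries equals `group_connectome_scale`.  The result is positive
definite with a comfortable margin *and* has the requested connectivity
amplitude.

**Subject deviations and repair.** Per-subject deviations remain
unstructured i.i.d. normal (symmetrised, and exactly centered across
subjects).  At `subject_sd = 0.1` they can still push the smallest
eigenvalue slightly negative; any non-positive-definite target is repaired
by flooring eigenvalues at `1e-6` and renormalising with `cov2cor` (the
flooring alone would lift the diagonal above 1).  The repair is logged as
a warning of class `fcrel_pd_repair`; with the default parameters its
entry-wise distortion is about 0.03 in z units, and the realised
connectome correlates with its target at r > 0.99.

**Noise and colouring.** Each region receives independent Gaussian noise
brick-wall filtered to `noise_band_hz` (default 0.001–0.1 Hz, matching the
analysis band) and scaled to unit SD.  The noise is coloured
cross-sectionally by the Cholesky factor of `C(t)`, held piecewise
constant over `state_window_trs = 10` TRs — a fidelity/cost trade-off: the
state process moves negligibly over 7.2 s, and per-window Cholesky
factorisations keep simulation of a 1250-volume, 50-region run under
0.2 s.  Because the colouring is cross-sectional it does not alter the
power spectrum: at least 95% of each series' power stays inside the band,
which is also what makes scrubbing cheap — at TR 0.72 s a 0.1-Hz-limited
series is ~7-fold oversampled, so randomly deleted volumes are largely
redundant.

**Task signal and nuisance.** Task conditions add a block-design common
signal (boxcar of period `block_seconds`, convolved with a canonical
double-gamma haemodynamic response, peak-normalised, amplitude in noise-SD
units) to the engaged regions — the "artificial synchrony" that task
timing induces.  Motion is modelled as 12 smoothed random walks, WM and
CSF as band-limited noise; all 14 leak into every region with weight
`nuisance_coupling` through random loadings.  There is deliberately no
cardiac/respiratory waveform modelling and no image-space displacement:
motion exists only as regressor leakage, which is the part the nuisance
regression stage can be validated against.

**Determinism.** Every run's random stream is derived from
`(seed, subject, condition, run)` by integer hashing, so any run can be
regenerated in isolation and cohort generation order is irrelevant.

## Default parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `tr_seconds` | 0.72 | multiband resting-state sampling interval |
| `duration_seconds` | 900 | 15-minute runs |
| `noise_band_hz` | (0.001, 0.1) | connectivity-relevant band; high edge well under Nyquist (0.69 Hz) |
| `group_connectome_scale` | 0.3 | SD of true group-mean z off-diagonals |
| `subject_sd` | 0.1 | SD of stable individual z deviations |
| `state_sd`, `state_timescale_seconds` | 0.1, 180 | minutes-scale connectivity-state fluctuation |
| `state_window_trs` | 10 | colouring window (7.2 s at default TR) |
| `nuisance_coupling` | 0.1 | leakage of motion/WM/CSF into ROI series |

The inter- and intra-subject variance amplitudes of real connectomes are
not pinned down by the test–retest literature; `group_connectome_scale`,
`subject_sd` and `state_sd` are calibration choices fixed once.  They put
single-run sampling noise (z-SD ≈ 0.075 for a 15-minute run), stable
individual differences (0.1) and group structure (0.3) in a realistic
ordering: individual differences are detectable but not dominant, and
baseline per-connection ICC across four 15-minute runs lands near 0.35–0.5
rather than at either extreme.

# Numerical and design choices

**Greedy packing rule.** A voxel becomes a new region center iff its
world-space distance to every already-selected center is at least
`spacing_mm`; anything closer is absorbed by an existing region.  This is
the only reading consistent with non-overlapping 5-mm-diameter regions.
The scan order defaults to ascending world z, then y, then x (inferior
voxels first), and is configurable; because the exact historical scan
order of any given mask is unknowable, a specific center *count* is not a
meaningful target — the properties that matter (pairwise spacing ≥ 5 mm,
maximality, partition of the mask) are tested exhaustively against a
brute-force oracle.

**Ties and erosion.** Distance ties in voxel assignment and coordinate
mapping break towards the lowest center index (deterministic).  "Surrounded
on all sides" for WM/CSF erosion is read as 6-face connectivity, the
conservative choice; 26-connectivity is available.

**Ideal filter.** The bandpass is a full-length DFT brick wall: band edges
inclusive, DC always removed, no windowing or padding.  It is idempotent
to 1e-10, which the tests assert.  For a 14-minute run the lowest
resolvable nonzero frequency (~0.0012 Hz) already exceeds the 0.001-Hz low
edge, so the low edge mostly coexists with DC removal.  Out-of-band
rejection of a non-bin sinusoid is limited by spectral leakage of the
finite record (energy ratio < 1%), not by the filter.

**Regression.** Covariates are regressed jointly (one OLS per region, with
an explicit intercept) rather than serially; each region series and each
covariate is detrended and filtered identically before the fit, and
rank-deficient designs drop collinear columns with a warning.  The stage
order — discard, detrend, bandpass, regress — is part of the contract:
reordering changes results.

**Fisher transform.** Correlations are clipped to `1 - 1e-7` in magnitude
before `atanh`, so duplicated series produce a large finite z rather than
infinity; values outside `[-1, 1]` beyond rounding tolerance are an error,
not a clip.

**ICC form.** The reliability metric is single-measure ICC(2,1) (two-way
random effects, absolute agreement) by default — the conventional choice
for test–retest fMRI where sessions are interchangeable random draws —
with ICC(1,1) and ICC(3,1) selectable; the form is recorded on every
result.  Subjects are rows and repeated runs are the sessions.  Negative
estimates are reported as computed so null simulations centre on zero.
The vectorised mean-squares path is checked against a direct-summation
two-way ANOVA oracle to 1e-10.

**Paired contrasts.** Runs are averaged within subject × condition (in z
units) before the paired t-test, because a test across subjects needs one
value per subject.  The BH family defaults to all tested connections;
connections with missing values are excluded from the family and the
family size recorded.  The "significance boundary" (smallest significant
|mean Δz|) is a property of each dataset and is reported per analysis, not
treated as a constant.

**Cross-subject correlation.** The normalisation is `1/(m-1)` with sample
standard deviations — the printed-formula reading — which makes the
statistic exactly the sample Pearson correlation across subjects.
Zero-variance connections are skipped and counted.

**Duration curve.** Sub-duration connectivity uses truncation from the
run start (matching the truncation semantics of the removal experiment);
window placement is configurable in principle but start-anchored windows
keep the nesting property that makes the monotonicity tests sharp.

**Removal order.** Preprocessing runs on the *intact* series and removal
afterwards, matching volume-censoring practice.  The alternative
(filtering the scrubbed, concatenated series) misreads the compressed
timebase — survivors spanning 15 minutes get indexed as 7.5 — so a
0.1-Hz brick wall then deletes the upper half of the genuine signal band.
Implemented that way, 50% scrubbing *lowered* mean ICC slightly more than
50% truncation on the synthetic cohort; with censoring-after-filtering
the scrubbing drop is about a fifth of the truncation drop, the expected
signature.  One shared removed-index set per run is used (deleting
different indices per region would break pairwise correlation alignment).

# Problem sizes used by the tests

The test-suite and acceptance analyses use cohorts sized so each
phenomenon is measured rather than assumed: 30 subjects × 50 regions ×
15-minute runs (TR 0.72 s) for the √time reproducibility law (durations
2/4/8/15 min) and the scrubbing-vs-truncation experiment (four runs,
state timescale 180 s); 200 subjects for the cross-subject null and the
ICC variance-ratio recovery (4 sessions); 40 subjects for the planted
task-contrast recovery (Δz = +0.3 on the 10 connections among five
engaged regions).  All seeds are fixed.

# What passing tests do and do not show

The generator reproduces the statistical *structure* the analysis relies
on — band-limited noise, stable individual differences, slow state
fluctuation, task-locked synchrony, nuisance leakage — not the spatial
richness of real data: no spatial autocorrelation beyond region
boundaries, no physiological waveforms, no susceptibility dropout, no
registration error, and motion that never moves the head.  Recovery of a
planted effect here validates the estimator chain (the code computes what
it claims); it does not certify effect magnitudes on any real dataset,
and real-data similarity or boundary values should be expected to differ.
Reliability maps over a real cortex additionally reflect tissue-boundary
averaging and susceptibility artifacts that have no synthetic analogue.

# Known limitations

- The slow state is a scalar process along one fixed direction matrix —
  the simplest mechanism with the right truncation-vs-scrubbing
  consequences; real state dynamics are higher-dimensional.
- Positive-definiteness repair, while mild at default amplitudes, means
  extreme parameter choices (large `subject_sd` or `state_sd` at large
  `n_rois`) realise a connectome slightly shrunk relative to the nominal
  ground truth.
- The greedy parcellation is sequential and exact; it is O(voxels ×
  centers) and intended for masks up to whole-brain size, not for
  repeated resampling loops.
- Connectivity tensors are kept in long tibbles, comfortable up to a few
  hundred regions; whole-brain 6923-region tensors (23.9 M connections
  per slice) should be processed per seed or per target subset.
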