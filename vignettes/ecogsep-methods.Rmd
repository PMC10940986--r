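---
title: "Methods: cross-channel separability of evoked and spontaneous ECoG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-channel separability of evoked and spontaneous ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogsep)
```

## The model

`ecogsep` quantifies whether a sensory stimulus changes the *distribution of
activity across cortical recording channels*, as opposed to evoking a
response at any single electrode. The object of analysis is the
instantaneous cross-channel vector: at sampling rate `fs` (1 kHz by
default), every sample of an `n`-channel recording is a point in
`n`-dimensional channel space. The claim being tested, for each stimulation
period, is that the cloud of points recorded 5–195 ms after stimulus pulses
is displaced or reshaped relative to the cloud of spontaneous points — even
though the two clouds may overlap heavily.

The analysis chain is:

1. **Artifact interpolation.** The electrical shock artifact is a short
   transient at the pulse time. The affected samples (1 ms by default,
   starting at the pulse sample) are replaced on every channel by the
   straight line joining the last untouched sample before and the first
   after the window. The operation is idempotent, and a separate 5 ms
   post-pulse exclusion during labeling covers residual artifact.
2. **Per-channel z-scoring** over the session (sample standard deviation,
   `n − 1` denominator; a zero-variance channel maps to zeros). Full
   standardisation is the default because channels of unequal gain would
   otherwise dominate the PCA; `center_only` is available.
3. **PCA over channels.** Components are the eigenvectors of the channel
   covariance, all retained (the embedding is a rotation, not a reduction —
   the point of the sensitivity analyses is precisely that discriminative
   information lives in *low*-variance components too). Computed via
   `stats::prcomp` (SVD); the test suite checks it against a direct
   eigendecomposition to 1e-8. Sign convention: the largest-magnitude
   loading of each component is positive.
4. **Labeling.** Evoked samples: windows `[pulse + 5 ms, pulse + 195 ms)`.
   The 190 ms width is the longest window that cannot overlap at a 5 Hz
   pulse rate, and is much longer than the 20–50 ms local evoked potential,
   so separability cannot be explained by that potential alone. Spontaneous
   samples are drawn from the two flanking spontaneous periods only, never
   within 195 ms after any pulse, matched in count to the evoked class. Two
   grouping schemes: evoked vs pooled spontaneous (2 groups, chance 50%),
   or evoked vs preceding vs following spontaneous (3 groups, chance 33%;
   restricted to pulse rates below 4 Hz, where the flanking periods hold
   enough data). In the three-group scheme each spontaneous class is
   matched to the evoked count, keeping chance at exactly 1/3.
5. **Min–max normalization** of each component to [0, 1], computed over the
   pooled points entering one analysis (not the whole session), so that no
   component is weighted by its variance in the nearest-neighbour metric. A
   constant component maps to 0.5.
6. **kNN separability.** k = 5 nearest neighbours under Euclidean distance,
   5-fold stratified cross-validation, repeated 100 times (500
   randomizations of train/test data per reported value); the spontaneous
   draw is refreshed every 10th repetition so the result does not reflect
   one particular subset of spontaneous activity. The summary accuracy is
   the mean over repetitions.
7. **Label-shuffle null.** Class labels are permuted over the same points
   (class counts preserved) and each permutation is scored by one full
   cross-validated evaluation; 100 permutations give the chance
   distribution. The empirical p-value uses the add-one correction,
   `p = (1 + #{null ≥ observed}) / 101`, so it is never exactly zero.
8. **Condition summaries.** Per-period accuracies are aggregated as medians
   per stimulation condition (all periods; per site; per frequency) and
   compared with two-sided Wilcoxon rank-sum tests, reported uncorrected by
   default (a Benjamini–Hochberg flag exists).

Ablation variants (`non_s1`: drop the single responding S1 electrode;
`left_hemi`: keep only the hemisphere without the evoked response) *re-fit*
the PCA on the retained channels rather than truncating the full-montage
basis: the analysis of a subset is an analysis of that subset's data.
Sensitivity analyses re-run the statistic with one component deleted
(`pc_knockout()`) or with only the leading `m` components
(`pc_incremental()`); the knockout analysis also reports the Pearson
correlation between a component's variance fraction and its accuracy drop.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `window_start_ms` / `window_end_ms` | 5 / 195 | ms | artifact guard; longest non-overlapping window at 5 Hz |
| `k`, `folds` | 5, 5 | – | conventional kNN/CV settings of the original analysis |
| `reps`, `resample_every` | 100, 10 | – | 500 randomizations; periodic spontaneous refresh |
| `shuffle_reps` | 100 | – | resolution of the permutation p-value (min p = 1/101) |
| `artifact_width_ms` | 1 | ms | interpolate between the samples immediately around the pulse |
| `sg_window_ms`, `sg_polyorder` | 20, 3 | ms, – | visualization smoothing only |
| `points_per_class` | `NULL` | samples | desk-scale subsampling (see below) |

## What the synthetic generator emulates

`simulate_session()` produces seeded sessions with the study's protocol
geometry: spontaneous periods (2 min) alternating with stimulation periods
(5 min) at 0.3–5 Hz on two alternating sites, frequencies ascending. The
signal model is:

* a **shared slow oscillation** near 1.6 Hz — the dominant rhythm under
  ketamine anesthesia — implemented as a sinusoid whose phase performs a
  Wiener random walk (`osc_phase_diffusion`, default 1 rad/√s). The phase
  noise gives the rhythm a realistic spectral width; a mathematically pure
  tone would phase-lock to periodic stimulation (at 1 Hz pulses it would be
  sampled at exactly five phases) and fabricate evoked/spontaneous
  structure that no physiological rhythm produces;
* **correlated Gaussian noise** with covariance
  `noise_sd² · ((1 − ρ)I + ρJ)` (ρ = 0.2) or any user-supplied positive
  semidefinite matrix, coloured through an eigendecomposition factor (valid
  for semidefinite covariances where a Cholesky factor is not);
* per pulse, a **one-sample shock artifact** on all channels (the waveform
  of a real stimulus artifact is equipment-specific; a single-sample
  impulse is a stand-in), a **damped negative half-sine evoked potential**
  (20–50 ms) on the single responding S1 channel, and an optional
  **global distribution shift**: a rank-one term
  `amp · gain(f) · pattern · env(t)` on all channels with a half-sine
  envelope of 200 ms — the time scale on which post-stimulus trajectories
  loop back to the spontaneous distribution.

The default shift `pattern` is the unit-norm alternating-sign vector over
channels. This is a deliberate choice: the shared oscillation occupies the
common-mode direction `(1, …, 1)/√n`, and a change in the *distribution* of
activity across channels — as opposed to a global offset — is a direction
orthogonal to that common mode. The default `gain(f)` is 1 below 2 Hz and
0.5 at and above, so sessions qualitatively reproduce stronger shifts at
low stimulation rates; both are configurable. Effect amplitudes are in
units of the background (oscillation amplitude 1, noise SD 0.5).

What the generator does **not** emulate: volume conduction and electrode
cross-talk, anesthesia-depth drift and other nonstationarities, 1/f
broadband structure, spatially graded evoked potentials, or any biophysics
of cortical networks. Passing tests therefore show that the pipeline
recovers the effects it models under realistic noise and rhythm — not that
real cortex behaves this way.

## Numerical choices and degenerate inputs

* **kNN determinism.** Distance ties break toward the lower training-point
  index (a stable sort); vote ties (possible with three classes) break
  toward the label of the nearest tied-class neighbour. The test suite
  holds the implementation to an exhaustive-search oracle on 200 random
  instances.
* **Fold assignment** is stratified and seeded, keeping fold-level chance
  at 1/G; the original toolbox's partitioning is not recoverable.
* **Constant rows/channels**: min–max maps a constant component to 0.5;
  z-scoring maps a constant channel to zeros.
* **Sample conventions**: a period `[start, end)` covers samples
  `round(start·fs)+1 … round(end·fs)` (1-based); the first pulse sits at
  the period start and the last strictly before its end, so a period of
  duration `T` at rate `f` holds exactly `floor(f·T)` pulses.
* **Artifact window**: `artifact_width_ms` of samples starting *at* the
  pulse sample (the artifact extends forward from the pulse); events at the
  recording edge are clamped with a warning.
* **Savitzky–Golay edges** use the filter matrix's off-centre full-window
  fits (the `signal` package convention), so output length equals input
  length without padding artifacts.
* **Seeds**: every stochastic step (simulation, spontaneous draws, fold
  splits, shuffles) derives from explicit integer seeds in its
  configuration object; `run_pipeline()` twice with the same seeds writes
  byte-identical result files.

## Open design points, and how they were decided

* **PCA scope.** Whether the embedding is fit once per session or per
  analysis window is not fully determined by the method description;
  default is per stimulation-period window (the period plus its flanking
  spontaneous periods), with `pca_scope = "session"` available. A per-window
  fit lets each analysis use the covariance structure of its own epoch.
* **Z-scoring scope** defaults to the whole session.
* **"Randomly chosen time series" of spontaneous activity** is read as
  contiguous segments of the evoked-window length (190 ms), drawn without
  overlap; isolated uniform samples are available via `spont_draw`.
* **Desk-scale subsampling.** Full-scale analyses use every evoked sample
  (tens of thousands of points per period). For test-sized runs,
  `points_per_class` subsamples the evoked windows to isolated samples —
  and then the spontaneous draw switches to isolated samples too. The two
  classes must share temporal structure: if one class is a handful of
  phase-coherent contiguous segments and the other is scattered samples,
  the point cloud is separable by autocorrelation alone and the label
  shuffle is no longer a valid exchangeability null.

## Known limitations

* At full scale the method compares contiguous evoked windows against
  contiguous spontaneous segments while shuffling labels at the *point*
  level. With strongly autocorrelated signals, points 1 ms apart nearly
  share coordinates and almost always share a label, so the point-level
  shuffle null is somewhat optimistic relative to a (hypothetical)
  segment-level permutation. This is a property of the statistic itself;
  the package's scaled analyses avoid it via symmetric isolated
  subsampling, and the type-I acceptance check runs in that regime.
* The global shift is rank-one with a fixed direction; real distribution
  shifts may rotate or expand the cloud instead of translating it.
* The empirical p-value's resolution is bounded by `1/(shuffle_reps + 1)`.
* Wilcoxon comparisons across conditions treat periods as exchangeable
  units pooled across sessions.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run on scaled sessions chosen to
exercise every code path in minutes on one CPU: one to two stimulation
periods of 20–120 s (instead of 5 min), 120–500 points per class
(subsampled from the full evoked windows), 10–100 repetitions and 100
shuffles, 20–40 seeded null sessions for the type-I rate, and 200 random
instances for the kNN oracle. Full-scale settings (the defaults:
`reps = 100`, `shuffle_reps = 100`, 120/300 s periods, no subsampling)
remain the configuration objects' defaults.
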