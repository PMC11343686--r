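---
title: "Methods: granule-cell temporal bases and climbing-fiber-driven LTD readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granule-cell temporal bases and climbing-fiber-driven LTD readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grcltd)
```

## The scientific question and the model

During a delayed-reward reaching task, cerebellar granule cells (GrCs)
develop activity profiles that span the delay between movement completion
and water reward, while climbing fibers (CFs) fire time-locked spikes when
the reward arrives. Classical GrC→Purkinje-cell (PkC) long-term depression
(LTD) weakens the synapses of GrC inputs active in the ~150 ms preceding a
CF spike. `grcltd` implements the analysis chain that asks: if reward-evoked
CF spikes drive LTD on a delay-spanning GrC basis, do the resulting synaptic
weights encode each GrC's *timing*, and does the implied PkC readout track
elapsed time through the delay?

The core computation, for each session:

1. For every included CF (one per imaged PkC dendrite) and every CF spike
   within $[0, 0.25]$ s of reward, tabulate each GrC's mean z-scored
   activity $F$ over the eligibility window $[-0.150, -0.025]$ s preceding
   the spike.
2. Bound each LTD event magnitude to $(0,1)$ with the logistic
   $1/(1+e^{-F/s})$, where $s$ is the cell's 95th-percentile fluorescence;
   by default $F$ is first rectified at zero so that only above-baseline
   activity drives LTD.
3. Average event magnitudes over all pooled (trial, spike) events, giving
   one GrC weight vector per PkC; normalize each vector to unit sum
   (standing in for homeostatic maintenance of total synaptic drive),
   subtract its mean (standing in for downstream interneuron inhibition),
   average across PkCs, and negate for the sign of depression.

The resulting session vector predicts the GrC→PkC weight pattern: GrCs most
active just before the CF teaching spikes end up most depressed, i.e. most
negative in the readout. Three null controls isolate what the temporal
structure contributes: LTD recomputed on time-shuffled GrC data (each
(cell, trial) keeps its value distribution but loses its timing), the true
weight vector randomly reordered across GrCs, and the uniform average.
An LTP extension treats the bottom 0.5% of each CF's rate timepoints as
potentiation events with the same eligibility window; the net per-synapse
tally is the LTD sum minus the LTP sum, so a CF with no sub-threshold
timepoints reduces exactly to the pure-LTD result.

## Signal conditioning

Raw fluorescence is conditioned in the standard order:

* **Bleach correction.** A double exponential
  $a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$ is fit to the frame-averaged
  fluorescence (Levenberg–Marquardt via `minpack.lm`) and every trace is
  divided by the fit (normalized to its initial value).
* **Percentile detrending.** A moving 10th-percentile baseline (10 s
  windows for GrCs, 5 s for PkC dendrites) is subtracted.
* **Noise z-scoring.** The noise center is a slow moving median (2 min /
  1 min) excluding samples above the cell's 99th percentile; the noise
  s.d. is a slow moving s.d. of the *sub-zero* residuals. Sub-zero
  residuals of Gaussian noise form a lower half-normal whose s.d. about its
  own mean underestimates the full $\sigma$ by $\sqrt{1-2/\pi}$; the trace
  is divided by the corrected $\sigma$ (the uncorrected variant is
  available via `half_normal_correction = FALSE`).
* **CF spike inference.** First-order inverse-kernel deconvolution
  ($d_t = f_t - f_{t-1}e^{-\Delta t/\tau}$, $\tau = 150$ ms) thresholded at
  1.9 s.d. of the deconvolved signal; consecutive-frame crossings merge
  into one event. Single-trial rates smooth the event train with a
  unit-area Gaussian kernel of 200 ms FWHM, with edge-clipped kernels
  renormalized so the rate integral always equals the event count.

Two numerical choices deserve note. Moving-window statistics use centered
windows with edge truncation, evaluated at strided anchors (1/16 of the
window) and linearly interpolated — the baselines they estimate vary on
timescales far slower than the stride. And the deconvolution threshold
scale is the *sample* s.d. of the deconvolved signal, not a robust
noise-floor estimate: a threshold of 1.9 robust (noise-only) s.d. would
admit ~2.9% of frames as false crossings on Gaussian noise (≈0.8 false
events/s at 30 Hz), swamping a ~1 Hz spike train. The sample s.d. is
inflated by the transients themselves, which places the same 1.9 multiplier
at a usable operating point; `sd_estimator = "mad"` restores the robust
variant for users who want it.

## Behavioral events

Reaches are segmented from the 200 Hz manipulandum y-position: reach *end*
is the first time within 0.5 mm of the episode maximum, the *midpoint* the
first crossing of 4 mm, and the *start* the latest time before the midpoint
at which the 100-ms-boxcar-smoothed speed (central differences) falls below
15 mm/s. Only reaches longer than 7 mm enter analysis. Trials with a lick
sensor high for >90% of any continuous 1.5-s block are excluded as stuck.
Lick rates smooth sensor 0→1 onsets with a 150 ms FWHM Gaussian. Two
summary metrics follow: the early/late delay preference
$(\text{late}-\text{early})/(\text{late}+\text{early})$ over
$[-0.8,-0.6]$ and $[-0.2,0]$ s, and the post-reward off-time (last time up
to 2 s at which the rate exceeds 70% of the peri-reward peak, defined as 0
when licking never falls below 50% of peak).

## Trial alignment and classification

Traces are sampled onto relative time grids by nearest-frame lookup,
aligned to reward, to the movement midpoint, or in a concatenated mode that
joins movement-aligned and reward-aligned segments so the movement midpoint
sits at $-\text{delay}$ on a reward-relative axis (the join is halfway
through the delay). Classification rules are window contrasts on
trial-averages: delay-active/reward-active cells additionally require a
paired signed-rank p < 0.05 and a mean difference above 0.2 z-scores;
anticipatory GrCs must exceed both the early-delay ($[-1.3,-1]$ s) and
post-reward ($[0.3,0.5]$ s) flanks by 0.1 z-scores in the late delay
($[-0.3,-0.03]$ s); reward CFs must exceed 0.1 (standardized rate units)
absolutely and relative to the pre-reward window. Rate tensors are
standardized per cell before thresholding so the 0.1 criterion refers to
the same scale as z-scored fluorescence. Against a 1 Hz Poisson background
with 100 trials, the reward-CF rule operates at an intrinsic ~10%
false-positive rate — a property of the magnitude-only rule, worth
remembering when interpreting small reward-CF fractions.

Timing metrics include the anticipation off-time (first post-reward time a
trace falls below 50% of its late-delay peak), the population CF onset
time (first time the across-cell average rate exceeds the 20th percentile
of the reward response; on omission trials, pass a threshold derived from
rewarded trials, since the omission trial's own reward window is empty),
the anticipatory center time (rectified-centroid of the trial-average over
the delay; an elevated-timepoint variant is available via
`method = "elevated_center"`), and the duration of elevated activity over
$[0,2]$ s relative to pre-movement baseline with a 0.1 z-score margin.

## The synthetic session generator

Because the recorded data are not packaged, every stage is validated on a
ground-truth generator (`synth_config()` / `simulate_session()`) that
emulates the statistical structure the analysis relies on. Defaults
describe an expert 1.1-s-delay session: 150 GrCs, 20 CFs, 100 trials, 20%
omissions, 30 Hz imaging, 200 Hz behavior, 34% anticipatory GrCs, 50%
reward-responsive CFs on a 1 Hz Poisson background, indicator decay 150 ms,
unit noise s.d.

**Behavior.** Self-initiated reaches ramp to an 8 mm virtual wall over
0.35–0.5 s, separated by 1.5–3 s gaps, with ~10% abortive (<7 mm) reaches
interleaved; reward follows reach end by exactly the delay on non-omission
trials. Licking is an inhomogeneous Poisson contact process (35 ms
contacts, 60 ms refractory) whose rate template ramps toward reward with a
post-reward consummatory burst in experts, and concentrates early in the
delay in novices; omission truncates post-reward licking.

**Anticipatory GrCs.** Expert profiles are long overlapping
piecewise-linear ramps on a movement-midpoint timebase: peak phase tiles
the learned span (basis delay + 0.2 s) uniformly; rise half-widths are
1.3–2.0 × the span scale; fall limbs decay linearly to a per-cell terminal
fraction of peak at reward (bounded fall rates so late-peaking cells do not
collapse just before reward). This family was chosen over narrow sequential
tiles because the analysis's central structure demands it: the activity
level in the 150 ms eligibility window must be a *graded* snapshot of each
cell's earlier timing — even for cells whose centers long precede the
window — while a cell's *overall* activity level must stay uninformative
about its timing so that time-shuffled LTD carries no timing signal. Narrow
tiles fail the first requirement (early cells decay to exactly zero and tie
at the logistic floor); families whose in-window activity mass covaries
with peak phase fail the second. Transient amplitudes are 2–5 z-scores
(bright somata); every cell additionally emits sparse spontaneous
transients (0.1–0.8 Hz, task-unrelated) and every (cell, trial) response is
scaled by a lognormal gain (sd 0.25) with ~50 ms trial jitter. Profiles
truncate ~0.2 s after reward and are prolonged by a per-cell 0.2–0.6 s on
omission trials. Novice anticipatory cells are brief (0.08–0.2 s rise),
weaker (0.6 × amplitude), loosely locked (120 ms jitter) early-delay
transients. Movement- and reward-transient classes (8% each) and silent
cells complete the population. Ground-truth center times are the
rectified centroids of the kernel-convolved canonical profiles over the
delay.

**CFs.** Poisson background at 1 Hz (halved during the delay for the
suppressed fraction), a reward spike with probability 0.8 within
$[0, 0.2]$ s of reward on rewarded trials, and on omission trials a late
spike near the prolonged anticipation off-time instead. Dendritic
fluorescence convolves the spike train with the indicator kernel
(peak-normalized; spikes are impulses) at 4–6 z amplitude. GrC *rate-like*
profiles use the area-normalized (DC-gain-1) kernel so sustained firing
keeps its amplitude.

**Noise.** Fluorescence noise is 20% white plus 80% AR(1) with the
indicator time constant (unit total variance × `noise_sigma`), emulating
correlated background (neuropil, slow motion) dominating bright-structure
imaging noise. Raw traces add slow two-sinusoid drift and a multiplicative
double-exponential bleaching envelope over a positive baseline.

**What the generator does and does not show.** Passing tests on this
generator demonstrate that the pipeline recovers the structure the
generator encodes at realistic SNR — they cannot certify performance on
features the generator lacks: real sessions have motion artifacts,
overlapping sources, non-Poisson CF statistics, richer behavioral
covariates (licking-locked GrC activity is explicitly absent), and
cell-to-cell correlations beyond the shared trial scaffold. One known
stylization: with a phase-diverse basis the noiseless anticipatory
*population average* rises through roughly the first 70% of the delay and
then plateaus near its maximum rather than rising strictly to reward;
recordings are dominated by late-peaking cells in a way this family, which
prioritizes uniform phase coverage (needed for the sorting-structure and
null-control properties), does not reproduce.

## Readout and decoding

The predicted PkC component is the weighted GrC sum per frame and trial.
Its timing is summarized two ways: the pooled correlation $r$ between
frame time and single-trial readout values, and the timing accuracy $R^2$,
the pooled coefficient of determination of the least-squares linear map
from readout to time (the squared pooled correlation). For display, the
trial-average is affinely mapped onto the window's time range. The optimal
reference is 10-fold cross-validated OLS decoding: trials are concatenated
along time, the target axis spans the delay, folds partition *trials* (not
frames, avoiding within-trial leakage), the fit includes an intercept, and
held-out predictions pool into $R^2$ and mean absolute error. Decoding
"after reward consumption" uses a $[1, 2]$ s post-reward window — the
epoch after consummatory dynamics — where a session should carry no
time-locked structure; the first post-reward second is dominated by
truncation and consumption transients and is deliberately not the default
null epoch.

## Design choices on genuinely open points

* *Pooled event averaging.* "Average over trials and timepoints" is
  implemented as the mean over all pooled (trial, spike) events; per-trial
  averaging differs when spike counts vary across trials.
* *Rectification default on.* Only above-baseline activity drives LTD
  (the logistic-only variant is `rectify = FALSE`; both are tested).
* *Logistic scale* is the 95th percentile of each cell's full-session
  z-scored trace (the tensor-based estimate is the fallback when a full
  trace is not supplied).
* *Omission trials contribute no LTD events*: withheld reward evokes no
  teaching spike, and the late omission-recognition spike is not a reward
  event (an `include_omission` flag exists).
* *All-to-all connectivity* between imaged GrCs and PkCs is assumed
  (`connection_prob` exposes the sparser alternative).
* *Mean subtraction before vs after cross-PkC averaging* commutes (both
  linear); subtraction is applied per PkC.
* *Uniform-control bookkeeping.* The mean-subtracted uniform vector is
  identically zero, so the `weight_set` keeps both a `session_vector`
  (obeying the normalization invariants for every provenance) and a
  `readout_vector` (the pre-subtraction uniform average for the uniform
  control).
* *Pipeline center masking.* The per-session weight-versus-center
  correlation uses only cells whose rectified delay-period trial average
  exceeds twice the trial-average noise floor ($2/\sqrt{n_\text{trials}}$);
  a "center of delay activity" is not meaningful for cells with no delay
  activity.

## Problem sizes and runtime

The test suite and the acceptance script run on deliberately scaled
sessions: the reference expert session uses 150 GrCs × 20 CFs × 100 trials
(~10 min of 30 Hz data), control-separation statistics use 20 seeds of
100 GrCs × 60 trials, and decoding contrasts 120 GrCs × 80 trials. These
sizes put every estimator comfortably in its asymptotic regime (binomial
fractions within a few percent, decoder fold-to-fold spread < 0.02 R²)
while keeping a full run to a few minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
library(grcltd)
report <- run_pipeline(list(seed = 1,
                            synth = list(n_grc = 150, n_cf = 20,
                                         n_trials = 100)),
                       output_dir = "expert_run")
report$classification$frac_anticipatory_grc
report$plasticity$ltd_center_spearman
report$readout$comparison
```

## Known limitations

The generator's stylizations above; the reward-CF rule's intrinsic
false-positive floor; linear-ramp profile families (no multiplicative
ramp curvature); no modeling of plasticity from spontaneous background CF
spikes (the spike-selection window is configurable, but the scientific
scope is reward-evoked teaching signals); and OLS-only decoding (the
decoder refuses ill-posed cell counts rather than silently regularizing —
a ridge variant is a natural extension).
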