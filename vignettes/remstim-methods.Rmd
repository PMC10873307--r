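---
title: "Closed-loop REM-sleep auditory stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop REM-sleep auditory stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(remstim)
```

remstim simulates and analyses eye-movement-locked auditory stimulation of
rapid-eye-movement (REM) sleep. During REM, bursts of saccadic eye
movements (EMs) appear on the electro-oculogram (EOG) as deflections of
roughly 50-100 µV. A closed-loop stimulator monitors one EOG channel and,
whenever the band-passed signal crosses an amplitude threshold while
stimulation is enabled, plays a short pink-noise click 100 ms later, then
pauses detection. A muted night (CNT) runs the identical detection protocol
with the sound off, giving a within-subject control for the stimulated
night (STM). The analysis layer quantifies what the clicks do to sleep
architecture, to the click-locked EEG (evoked potentials and time-frequency
power), and to overnight memory consolidation measured by three behavioural
tasks.

Every stage of that chain is implemented here against *synthetic*
polysomnography with known ground truth, so the full pipeline is testable
offline. This vignette documents the models, the tunable parameters, and
the numerical decisions.

## The synthetic polysomnography generator

`generate_hypnogram()` draws a bout-structured stage sequence over
{W, N1, N2, N3, R} in 30-s epochs. Bout stages are sampled in proportion to
each stage's *unfilled* share of its target epoch count and bout lengths
from a shifted Poisson (default mean 300 s), so empirical stage fractions
converge to the request as the night grows while retaining a realistic
run-length structure. The default fractions put about 18.3% of sleep time
in REM at ~92% sleep efficiency, i.e. the control-night architecture the
package's summaries are designed to reproduce. Arousal (8/h in sleep) and
artifact (4/h) annotations are drawn as Poisson events with uniform
durations (3-15 s and 1-10 s).

`generate_rem_eog()` places biphasic raised-cosine saccade pulses (0.3 s
wide, amplitude uniform in 50-100 µV, sign random) at Poisson times (6/min
by default) restricted to R epochs, over pink background noise of 5 µV
RMS. Saccades closer than 0.6 s to their predecessor are thinned so that
individual deflections remain resolvable by a detector with a 0.5 s
refractory. The returned onset times are the exact ground truth used by
recall/precision checks. No published waveform exists for these saccades;
only the amplitude interval matters to a threshold detector, so the pulse
shape is a free design choice.

`generate_eeg_with_responses()` builds each EEG channel as 1/f-coloured
Gaussian noise at 30 µV RMS — chosen so that injected effects sit at a
realistic signal-to-noise ratio — with the theta band multiplied by 1.3
during R epochs (a light stage dependence). Click-locked effects come from
a `click_effects()` description:

* an additive evoked potential — a Gaussian P2 bump (latency 275 ms, width
  45 ms, amplitude 8 µV) and a sustained negativity (-3 µV, 0.5-1.5 s);
* multiplicative band-power modulations — +1 dB in the beta band (15-25 Hz)
  over 0.2-1.4 s and -1 dB in the theta band (4-8 Hz) over 0.7-1.5 s, with
  100 ms cosine ramps.

The band modulations are applied by exactly partitioning the background
into the target band and its complement with an FFT mask and scaling the
band component inside the effect window, so the decibel transform of the
analysis recovers the injected dB directly. The P2 amplitude default of
8 µV is the smallest realistic value that a ~100-trial average resolves
against the 30 µV background (about 3 SD of the averaged noise); a smaller
bump would make the generator's own evoked response undetectable by
construction. Setting all amplitudes to zero (`null_click_effects()`)
yields pure background, which the calibration tests rely on.

`generate_behavioural_dataset()` simulates the three tasks per subject,
condition (CNT/STM) and session (pre/post). Visual discrimination (VDT)
trials are Bernoulli draws from a cumulative-Gaussian psychometric curve
(guess rate 0.5, lapse 0.02, slope sigma = 40 ms) over the standard SOA
block ladder (two 50-trial blocks at 400/300/200/160 ms, three at
120/100/80/60/40 ms); mirror-tracing (MTT) on-path times are log-normal;
psychomotor vigilance (PVT) reaction times are shifted log-normal above a
100 ms floor. Condition effects enter as target overnight gains: the
morning performance parameter is the evening one scaled by 1 - gain/100.
Defaults encode +20.71 percentage points of differential VDT gain for STM,
-11.60 for MTT, and none for PVT — the condition contrasts the statistics
layer is designed to detect. What the generator does *not* emulate:
sequential learning within sessions, fatigue, inter-task interference, or
any EEG-behaviour coupling; passing tests therefore validate the pipeline's
estimators and error control, not claims about real sleep data.

## Filters

All four band-pass filters are Chebyshev type II designs specified by their
3 dB passband edges, stopband edges, and minimum stopband attenuation
(single pass):

```{r}
filter_specs()
```

The design runs entirely in zero-pole-gain form — analog prototype,
lowpass-to-bandpass transform, bilinear transform — and is realized as
second-order sections. Transfer-function polynomial form is numerically
unusable here: a 0.05 Hz edge at 500 Hz sampling puts poles at radius
~0.9999, where high-degree polynomial coefficients lose all precision. The
minimum order comes from the analytic Chebyshev order formula at the
binding stopband selectivity; the prototype is then scaled to reach the
required attenuation just inside the binding specified stopband edge, with a
0.999 scaling margin so both passband and stopband figures are met
strictly in floating point. `magnitude_response()` evaluates the transfer
function exactly from the zeros and poles.

The registry's specifications are single-pass targets; zero-phase
(forward-backward) application doubles attenuation in dB. Zero-phase
filtering uses odd-reflection edge padding *plus* steady-state initial
conditions per biquad. Padding alone cannot work at these edges: startup
transients of near-unit-circle poles decay over ~10^4 samples, so the
initial state of each section is set to its constant-input steady state
scaled by the first (padded) sample, the same construction scipy's
`filtfilt` uses.

```{r}
d <- design_cheby2_bandpass("online_eog", fs = 500)
magnitude_response(d, c(0.1, 0.3, 1.2, 5, 15))
```

## The closed-loop detector

`run_em_detector()` reproduces the online rule: while enabled and not
paused, the first sample whose absolute amplitude reaches the threshold
logs a detection, and a click follows 100 ms later; detection then pauses
for `refractory_s` after the stimulus. The default pause is 2.0 s; the
protocol is also described with a 2.5 s pause in places, so the value is a
config knob rather than a constant. Crossing semantics are
first-sample-at-or-above on absolute amplitude; on continuous-valued data
ties are impossible and >= makes the rule deterministic. The
implementation scans threshold crossings forward-greedily, which is
sample-for-sample equivalent to the streaming state machine — hence causal,
verified by truncation-equivalence tests. The muted condition logs
identical events flagged `muted`.

`gate_stimulation()` is a deterministic surrogate for the human operator,
who enabled stimulation after a stretch of stable REM and disabled it at
any stage change or arousal: `stim_on` after `stable_epochs` (default 2)
consecutive R epochs, `stim_off` at the next non-R epoch or annotated
arousal onset. The human operator's judgement — waiting for a few saccades
with quiet chin muscle tone — is not machine-precise; a run-length rule is
the reproducible surrogate.

`stimulation_accuracy()` reports the percentage of clicks inside R epochs
and the percentage falling within the triggering saccade's extent (onset
to onset + 0.3 s, the generator's pulse width). The click falls on its
trigger only when the crossing occurs early in the pulse, so this
percentage is expected to be well below 100 even under perfect gating.

## Evoked responses

`epoch_trials()` cuts -2 to +3 s trials around each click and excludes
candidates whose click is outside stage R, whose window is closer than 2 s
to an arousal/artifact annotation, or which collide with the record edge;
each exclusion carries one primary reason, checked in that order.
`interpolate_channels()` replaces bad channels by spherical-spline
estimates (order m = 4, 50 Legendre terms, ridge 1e-5 — values in the
common range for scalp interpolation) from the remaining channels of the
21-site 10-20 montage, and rejects the trial instead when bad channels
reach 25% of the electrodes.

`compute_ersp()` convolves each trial with unit-gain analytic Morlet
wavelets of 6 cycles on a 0.25-30 Hz grid (0.25 Hz steps), trims to -1 to
+2.5 s, divides each trial's linear power by its own baseline mean (-1 to
0 s) per channel and frequency, and converts to dB. Wavelet normalization
cancels in the baseline ratio, so the dB map is invariant to rescaling the
raw microvolts (tested to machine precision). Two numerical caveats are
deliberate:

* Below about 1.2 Hz a 6-cycle wavelet outlasts the 1 s edge buffer left
  by the trim; those rows are computed but flagged (`unreliable_freqs`).
* A single trial's log power carries a constant negative bias relative to
  mean power (the mean of log of an exponential variable). The bias is
  shared by the baseline and post-stimulus parts of the map, so
  stimulus-locked modulation is read as the change against the same map's
  baseline rows (`ersp_band_change()`), which is unbiased under
  stationarity. Averaging linear ratios instead would carry a
  frequency-dependent positive bias from the reciprocal of the baseline
  mean (few effectively independent baseline samples at low frequencies),
  which is why the map stays in dB.

The power envelope is smooth at these bandwidths, so maps are stored on a
decimated time grid (20 ms default).

## Cluster statistics

`permutation_cluster_test()` compares paired subject-level ERP (1-D) or
ERSP (2-D) maps: pixels where a two-tailed Welch t between conditions has
p < 0.05 are grouped into connected components (4-connectivity in
freq-time, 2-neighbour in 1-D; connectivity is a convention choice),
positive and negative t separately, and each cluster's *pixel count* is
referred to the permutation distribution of the maximal suprathreshold
cluster size under within-subject condition relabelling. The default 1600
permutations are sampled without repetition; when 2^n does not exceed the
request the test enumerates all sign patterns (exact at n = 4, verified
against a brute-force oracle). Cluster p-values use +1 smoothing,
(1 + #{null >= observed}) / (1 + n_perm), so p = 0 is impossible. The
within-subject sign-flip scheme is the natural reading of relabelling
paired conditions. Cluster mass is the more common statistic elsewhere;
pixel count is used here because that is the statistic this pipeline
defines, and `cluster_power_per_electrode()` exposes both the mean and the
median of in-cluster dB per electrode, since both summaries are in use.

At desk scale the calibration checks run on reduced problems (10 subjects,
12 x 20-pixel maps, 256 permutations, 200 null experiments); the max
cluster-size statistic is discrete, which makes the test slightly
conservative at small map sizes.

## Behavioural scoring and the statistics layer

PVT: mean reaction time over the closed interval [100, 500] ms (the
validity rule names its endpoints ambiguously; closed is the deterministic
reading). VDT: maximum-likelihood cumulative-Gaussian psychometric fit on
letter-task-correct trials with guess rate fixed at 0.5 and lapse bounded
in [0, 0.06]; the score is the SOA where the fitted curve reaches 80%.
The likelihood is aggregated to binomial counts per SOA level and fitted
from several starts (a data-driven midpoint guess at two slope scales plus
a broad fallback) because the likelihood surface has local optima that
bias a single-start threshold by ~10 ms. Thresholds outside
[min SOA / 2, 2 max SOA] or non-convergent fits are flagged, not dropped
silently. MTT: mean log on-path time after removing trials more than 3.5
*pooled-group* standard deviations from the group mean. Overnight gain is
exactly 100 x (evening - morning) / evening with no per-task sign
flipping; for measures where smaller is better (RT, threshold SOA) a
positive gain is an improvement, and whether a larger MTT log-time is
better is left to interpretation, as the measure's direction is genuinely
ambiguous.

The comparison layer gates paired tests on the Shapiro-Francia statistic
of the paired differences at alpha = 0.05 (gate level and target vector
are conventions chosen here): paired t when normality is not rejected,
exact Wilcoxon signed-rank (n <= 25, zeros dropped) otherwise; proportion
data are logit-transformed first. The gain models
(gain ~ condition + stage minutes, condition coded CNT = 0 / STM = 1 to
a convention that keeps the reported model signs interpretable) are ordinary least squares, while
electrode-wise power-vs-gain fits use Huber's M-estimator (tuning 1.345
for 95% Gaussian efficiency, MAD scale, IRLS to 1e-8 or 100 iterations)
with Benjamini-Hochberg FDR across the 21 electrodes; where the robust/OLS
choice is ambiguous both are exposed and these are the defaults.
`power_analysis_paired_t()` finds the smallest N whose exact noncentral-t
power reaches the target by integer search (19 at d = 0.7, alpha = 0.05,
power 0.8).

## Worked micro-example

```{r}
night <- synthetic_night(duration_min = 20, fs = 125, seed = 2,
                         channels = c("Fz", "Cz"))
sleep_summary(night$hypnogram)
stimulation_accuracy(night$events, night$hypnogram, night$em_times_s)
```

```{r}
d <- design_cheby2_bandpass("offline_eeg", 125)
eeg_f <- lapply(night$signals[c("Fz", "Cz")], apply_filter, design = d)
trials <- epoch_trials(eeg_f, night$events, night$hypnogram)
trials
if (dim(trials$data)[1] >= 2) {
  e <- compute_ersp(trials, freqs = seq(2, 30, by = 1))
  round(c(beta_db = ersp_band_change(e, c(15, 25), c(0.2, 1.4)),
          theta_db = ersp_band_change(e, c(4, 8), c(0.7, 1.5))), 2)
}
```

## Problem sizes and limitations

The shipped tests exercise the pipeline at reduced scale chosen as the
package's own verification conditions: nights of 20-60 min, sampling rates
of 100-250 Hz, single- to four-channel montages, 28-240 trials per ERSP
run, 200-experiment calibration batches with 256 permutations, and
80-run bootstrap coverage batches. The acceptance script's quantities are
deterministic filter-design figures computed at the full 500 Hz.

Known limitations: the generator does not model spindle/slow-oscillation
morphology, realistic NREM microstructure, subject-level EEG-behaviour
coupling, or hardware audio latency beyond the fixed 100 ms delay; EDF
support covers continuous 16-bit recordings with per-channel rates (what
the fixtures need), not the full EDF+ annotation format; sub-1.2 Hz ERSP
rows are flagged rather than corrected; and the operator-gating surrogate
is a deterministic rule standing in for a human judgement, so accuracy
percentages on synthetic nights exceed what a human-in-the-loop system
reports.
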