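---
title: "Methods: simulating and analysing 40 Hz flicker entrainment in sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing 40 Hz flicker entrainment in sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Rhythmic visual stimulation at 40 Hz ("gamma flicker") drives a steady-state
visually evoked potential (SSVEP): an EEG oscillation phase-locked to the
flicker. Delivering the flicker through closed eyelids during sleep raises
two measurement questions that this package addresses end to end:

1. **Does the stimulus evoke 40 Hz activity in each sleep stage?** Measured
   in the frequency domain as the spectral density power at exactly 40 Hz
   (*PSD40*, in dB) and in the time domain as the peak-to-trough amplitude
   of the average 25 ms stimulus-locked waveform (*SSVEPamp*, in uV).
2. **Is the measured 40 Hz activity genuinely stimulus-driven?** Gamma-range
   EEG is notoriously confounded by muscle, ocular and electrical artifacts.
   Two signal-to-noise constructions address this: a neighbour-band ratio
   for PSD40 and a shuffled-segment permutation null for SSVEPamp, plus an
   electrically-matched control condition (LED circuit driven, light
   masked) and a linear-interpolation control for LED transients.

Because the package must be testable without any recording hardware, a
first-class synthetic polysomnography generator produces whole "nights"
with known ground truth; every downstream claim is validated by parameter
recovery against that truth.

# The analysis chain

Preprocessing follows the standard chain for this paradigm: band-pass
filtering 0.16–300 Hz (zero-phase cascade of 4th-order Butterworth
high-pass and low-pass sections), bad-channel rejection, averaging of the
occipito-parietal region of interest (O1, Oz, O2, PO3, POz, PO4),
re-referencing to the mastoid average (A1, A2), segmentation into 30 s
epochs, and bad-trial rejection: an epoch is discarded if its peak-to-peak
amplitude exceeds 1 mV, its sleep-scoring certainty is below 50%, or — for
experimental-condition epochs in the spectral analysis — fewer than 25 s of
visible stimulation overlap it. Condition-by-stage bins follow the session
design: control bins from the control night (session 2), the experimental
wakefulness bin from the dedicated wake stimulation block (session 1), and
experimental N2/N3/REM bins from the stimulation night (session 3). N1 is
scored but never analysed.

**PSD40.** Each surviving 30 s epoch gets a single-taper Hamming
periodogram with density scaling; the 1/30 Hz grid contains a bin at
exactly 40 Hz, which is extracted without interpolation. Epoch spectra are
averaged on the *linear* power scale before conversion to dB (averaging dB
values is biased low); dB is referenced to 1 V²/Hz with uV-to-V conversion,
which puts sleep EEG near −135 dB. The spectral SNR divides the linear
power at 40 Hz by the mean linear power over the flanking bands
[38, 39.5] and [40.5, 42] Hz (bounds inclusive). We deliberately form this
ratio on the linear scale: dividing *negative* dB values would invert the
interpretation that values near 1 mean "indistinguishable from neighbours".

**SSVEPamp.** Every 25 ms interval time-locked to an LED-ON edge is one
segment (contiguous, non-overlapping; the LED clock is phase-locked to the
recording start). Fade-in/fade-out intervals are excluded; in the control
condition the masked LEDs' electrical clock supplies "virtual" edges over
the whole mask-on recording. Segments spanning more than 100 uV are
rejected (strictly: exactly 100 uV survives); the rest are averaged
per-sample and the amplitude is the raw max − min of the average — no
fitting, no smoothing. The permutation SNR shuffles the sample order
independently within every segment (fresh permutations each of 100
repeats), averages, takes the peak-to-trough of each "random" SSVEP, and
divides the true amplitude by the mean random amplitude.

**Sleep metrics.** TST is 0.5 min per non-W epoch; WASO counts W epochs
strictly between the first and last sleep epoch (wake before onset and
after the final sleep epoch is excluded — the definition is applied
literally); stage percentages are of TST; REM latency is referenced to
sleep onset (first non-W epoch), the conventional definition. GSQS items are consumed as already-keyed binaries
(0–14 sum) so no copyrighted item text is embedded.

**Statistics.** Paired condition contrasts use an assumption-gated choice:
Shapiro–Wilk on the pair differences (alpha .05) and a 3 × IQR outlier rule
select between the paired t-test (effect: Cohen's d~z~ with a
noncentral-t-inverted 95% CI) and the Wilcoxon signed-rank test (effect:
matched-pairs rank-biserial r with a normal-approximation CI). The
stage-level multilevel comparison uses repeated-measures ANOVA (partial
eta-squared, noncentral-F CI, Tukey post-hoc on the within-subject error
term) when per-level normality, outliers and Mauchly sphericity pass, and
Friedman otherwise (Kendall's W with a seeded subject-bootstrap CI,
pairwise signed-rank post-hocs with Bonferroni–Holm). The 3 × IQR rule and
the CI constructions are package choices where such protocols typically name only
"outliers" without a rule; each branch records which correction
applied. One-tailed contrasts are fixed as experimental > control. The
power tool is simulation-based with the test family exposed as a parameter
(plain t, Wilcoxon, or the full gated branch), because simulation-based
sample-size plans in this literature often embed nonparametric tests or
multiplicity assumptions that closed forms do not capture; no particular
reproduction is hard-coded.

# The synthetic night generator

A rendered night consists of 12 channels (6 ROI, 2 mastoids, 2 EOG, 2 EMG)
at a sampling rate that must be a multiple of 40 Hz (default 1000), so each
flicker cycle is an integer number of samples.

**Hypnogram.** First-order Markov chain over {W, N1, N2, N3, REM} on the
30 s epoch grid, with a transition matrix calibrated so the stationary mix
matches a healthy young adult: about 421 of 480 min asleep, with N1 ≈ 9%,
N2 ≈ 53%, N3 ≈ 17%, REM ≈ 21% of total sleep time. Sleep-protocol nights
are redrawn (deterministically under the seed) until at least one N3 epoch
exists, so the stimulation trigger can fire. Scoring certainty is
Beta(10, 2) per epoch (mode 0.9), which makes the <50%-certainty rejection
rule exercisable without dominating.

**Stimulation schedule.** The sleep protocol starts stimulation at the
first N3 epoch with a 300 s raised-cosine illuminance ramp; any W or N1
epoch triggers a 5 s fade-out; stimulation stays off until six consecutive
epochs scored neither W nor N1 have passed, then restarts (with a fresh
full ramp rather than resuming from a partial level)
at the start of the following epoch. The 40 Hz/50% duty LED square wave
runs whenever illuminance is non-zero; fades modulate amplitude only. The
wakefulness protocol drives the LEDs at full level from the start of the
block with no ramp: realistic wakefulness trial counts (tens of thousands
of segments from two 10-minute blocks) require essentially the whole block
to contribute segments. Control nights keep the LED circuit
active for the entire recording with zero illuminance (masked LEDs) — the
electrically matched control.

**Evoked response.** A 40 Hz sinusoid (optional 2nd harmonic, default off)
with a 4 ms latency, added to the ROI channels only, scaled by the
configured stage amplitude and the instantaneous illuminance. Defaults are
the peak-to-trough values typical of this paradigm: W 0.96, N2 0.08,
N3 0.07, REM 0.09 uV. The sampled template is normalised so that its
on-grid peak-to-trough equals the configured amplitude exactly; recovery is
therefore unbiased at the sample level at any admissible sampling rate, and
the only recovery error is the noise bias of the range statistic
(see below).

**Noise model and its calibration.** Each ROI channel is a shared 1/f²
background (RMS 4 uV, flat below 1 Hz) plus a shared flat broadband floor
(0.005 uV²/Hz) plus stage oscillations (10 Hz alpha in W, 13 Hz spindle
events in N2, a 0.75 Hz slow oscillation in N3, weak theta in REM) plus
white sensor noise (1 uV). During W epochs an additional tonic broadband
floor of 0.15 uV²/Hz emulates waking muscle tone. Mastoids carry their own
1/f² background (2 uV). These five numbers are pinned jointly by four
constraints rather than chosen freely:

* the control-night PSD40 magnitudes (wake near −128 dB, sleep near
  −136 dB re 1 V²/Hz);
* control-condition SSVEPamp of order 0.02 uV at realistic segment counts
  (the expected range of a noise-only average);
* calibration of the permutation null: a *pure* steep-1/f spectrum makes
  the shuffled null systematically exceed the stimulus-coherent numerator
  (slowly varying noise inflates within-segment variance while contributing
  almost nothing at harmonics of 40 Hz), so the spectrum must carry a flat
  high-frequency floor — exactly what scalp EMG and amplifier noise provide
  in real recordings; and
* recoverability of the injected sleep-stage amplitudes within 10% at
  2 × 10^5 segments.

**Artifacts.** EMG bursts (0.5 s, white-carrier, four-fold rate in W) and
slow ocular deflections (1 s, W/REM only) are inserted at configurable
rates, on their source leads with a fixed bleed into the ROI. The optional
LED electrical artifact is a symmetric biphasic transient at every LED
on/off edge, present whenever the circuit is active — including control
nights — with channel-specific coupling gains (Oz exactly 1): electrical
pickup is not spatially uniform, so mastoid re-referencing attenuates but
cannot cancel it. A spatially uniform artifact would vanish identically
under re-referencing and could never be detected by the control analysis.

# Estimator properties worth knowing

**Range-statistic bias.** SSVEPamp is max − min of a noisy average, which
is biased upward by roughly twice the per-sample standard error of the
averaged waveform. At the default noise, recovering a 0.07 uV sleep-stage
amplitude within 10% therefore needs of the order of 2 × 10^5 segments —
the package's recovery checks use exactly that scale. Control-condition amplitudes of ~0.02 uV at such trial counts should be
read as this noise floor, not as a residual response.

**Sampling-rate dependence of the permutation null.** The shuffled null
draws on the full within-segment variance, while the true average retains
only noise at harmonics of 40 Hz inside the pass band. With a flat floor up
to the 300 Hz band edge, twelve harmonics contribute at 1000 Hz sampling
and the null is calibrated (medians near 1); at 200–400 Hz sampling only
one or two harmonics survive and the null ratio is structurally biased
low. Null-calibration checks therefore run at 1000 Hz; amplitude-recovery
checks, which do not involve the permutation null, run at 400 Hz where
they are cheaper and the range bias is smaller.

**LED artifact vs. the analysis band.** A 2 ms biphasic transient lives
mostly above 250 Hz; the 0.16–300 Hz zero-phase filter both attenuates it
and smears it over ±2 ms. The interpolation control therefore uses a 3 ms
window by default in the package's own controls (68% amplitude removal,
3% distortion of the underlying sinusoid). The invariance check "amplitude
unchanged after interpolation" is meaningful at the wakefulness response
scale (~1 uV); the filtered artifact residual is of the same order as the
sleep-stage SSVEP amplitudes themselves, so no processing step could leave
those unchanged in the presence of a substantial artifact.

# Numerical and degenerate-case choices

* Epochs are half-open `[k·30 s, (k+1)·30 s)` with 0-based indices; 30 s at
  any admissible rate is an integer number of flicker cycles, so segments
  never straddle epochs.
* Zero-power spectral bins are floored at −400 dB with a message; the
  40 Hz bin is matched exactly (tolerance 10^-6 Hz) and missing bins are an
  error, never an interpolation.
* All-zero paired differences return p = 1 with a zero effect and a flag;
  constant differences make Shapiro–Wilk undefined and route to the
  nonparametric branch.
* A hypnogram without sleep yields TST = WASO = 0, undefined latencies and
  a `no_sleep` flag.
* EDF output digitises against the physical min/max *as written into the
  8-character header fields*, so a write/read round trip is exact to one
  16-bit quantisation step.
* Bad-channel outlier detection compares like with like (robust z of
  log-variance among ROI channels, MAD floored at 0.2 log-units); mastoid,
  EOG and EMG leads are only flat-checked.

# What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on: stage-
dependent spectra and evoked amplitudes, the closed-loop schedule with its
fade semantics, scoring uncertainty, segment-count asymmetries between
conditions, artifact time-locking, and an electrically matched control.
It does **not** emulate real-EEG nonstationarity beyond stage bouts,
inter-subject variability in spectra or eyelid transmission, topographic
spread, scorer disagreement structure, sleep-architecture responses to the
stimulation itself (the generator's sleep is identical across conditions
by construction, so between-night sleep-quality contrasts are null except
for the questionnaire, which is simulated with condition-dependent item
probabilities), or the first-night effect. Passing recovery tests therefore
demonstrates the correctness and calibration of the *pipeline*, not the
physiology of any particular dataset.

# Problem sizes used by the test-suite and acceptance runs

Chosen as the smallest scales at which each property is statistically
decidable: 20 seeded 15-minute control nights at 1000 Hz for null
calibration; six seeded stimulated recordings pooled per stage for the
stimulated-SNR checks; ~2 × 10^5 segments per sleep stage (and 10^5 for
wakefulness) at 400 Hz for amplitude recovery; 20 000 simulations for
type-I calibration and 50 000 for the power cross-check; and a six-subject
study (2 h nights at 400 Hz) for the end-to-end reproduction script.

# Known limitations

The Markov hypnogram has no ultradian cycle structure; REM bouts can occur
earlier than physiologically typical. The spectral model is piecewise
stationary within stage bouts. The Friedman-branch Kendall's W confidence
interval is a subject-level bootstrap, which is conservative at very small
n. The EDF writer emits the plain 16-bit variant only, with one-second
records and a single common sampling rate.
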