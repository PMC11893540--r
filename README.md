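# gammaflick

Analysis of 40 Hz visual flicker entrainment in sleep EEG.

Rhythmic visual stimulation at 40 Hz ("gamma flicker"), delivered through
closed eyelids during sleep, drives a steady-state visually evoked
potential (SSVEP) — an EEG oscillation phase-locked to the flicker. This
package implements the complete measurement pipeline for such experiments,
for researchers who need to quantify stimulus-evoked gamma activity per
sleep stage while ruling out muscle, ocular and electrical confounds:

* a **synthetic polysomnography generator**: whole nights of 12-channel
  EEG/EOG/EMG with a first-order-Markov hypnogram, stage-specific spectra
  (alpha, spindles, slow oscillations), a closed-loop stimulation schedule
  (trigger at the first N3 epoch, 300 s raised-cosine fade-in, 5 s fade-out
  on arousal, restart after six consecutive non-W/N1 epochs), an injected
  40 Hz evoked response with known per-stage amplitude, artifacts, and an
  optional electrical LED transient — plus the ground truth for parameter
  recovery;
* **preprocessing**: EDF/CSV input-output, zero-phase 0.16–300 Hz
  band-pass, bad-channel rejection, occipito-parietal ROI averaging with
  mastoid re-referencing, 30 s epoching, and bad-trial rejection
  (>1 mV peak-to-peak, <50% scoring certainty, <25 s stimulation);
* **frequency domain**: per-epoch Hamming periodograms averaged on the
  linear scale; the power at exactly 40 Hz in dB (**PSD40**) and its
  neighbour-band SNR (40 Hz power over the mean of [38, 39.5] ∪
  [40.5, 42] Hz);
* **time domain**: 25 ms stimulus-locked segments (one per flicker cycle),
  >100 µV segment rejection, the grand-average SSVEP and its peak-to-trough
  amplitude (**SSVEPamp**), a 100-repeat shuffled-segment permutation SNR,
  and a linear-interpolation control for LED electrical transients;
* **sleep metrics**: TST, WASO, stage percentages, sleep-onset and REM
  latency, GSQS sum scores;
* **statistics**: assumption-gated paired tests (paired t with Cohen's
  d<sub>z</sub> vs Wilcoxon signed-rank with rank-biserial r, both with 95%
  CIs), repeated-measures ANOVA vs Friedman for stage contrasts (η²,
  Kendall's W, Tukey/Holm post-hocs), Bonferroni–Holm correction, and
  simulation-based power analysis.

`run_pipeline()` chains everything over a multi-subject synthetic study,
deterministically under one seed.

## Worked example

Simulate one experimental night (1 h at 400 Hz for speed), preprocess it,
and extract the N3 results:

```r
library(gammaflick)

cfg <- sim_config(sampling_rate = 400, night_duration = 3600, rng_seed = 7)
night <- render_night(cfg)
night$hypnogram
#> <hypnogram> 120 epochs (60 min): W=20 N1=3 N2=54 N3=43 REM=0

pre <- preprocess_night(night$recording, night$hypnogram, night$stim_log,
                        condition = "experimental", session = 3)
es <- pre$epochs
n3 <- epoch_subset(es, which(es$meta$stage == "N3" & !es$meta$rejected))
bin_psd40(n3)
#> <psd40_result> experimental/N3: PSD40 = -136.15 dB, SNR = 1.68 (42 epochs)

keep <- intersect(pre$ssvep_keep, es$meta$epoch_index[es$meta$stage == "N3"])
bin_ssvep(pre$roi, night$stim_log, keep, "experimental", "N3", seed = 1)
#> <ssvep_result> experimental/N3: amplitude 0.0778 uV over 39600 segments; shuffle SNR 3.12

summarize_hypnogram(night$hypnogram)
#> <sleep_summary> TST 50 min, WASO 9.5 min, SOL 0.5 min, REM latency NA min
#>   % of TST: N1=3 N2=54 N3=43 REM=0
#>   flags: no_rem
```

Reading the output: the N3 40 Hz power sits near −136 dB (re 1 V²/Hz) with
a neighbour-band SNR above 1 — the 40 Hz bin stands out from the
surrounding 38–42 Hz background, as expected under stimulation. The
stimulus-locked average over 39 600 cycles has a peak-to-trough amplitude
of 0.078 µV, close to the 0.07 µV the generator injected for N3, and a
permutation SNR well above 1 — the averaged waveform carries genuine
temporal structure locked to the flicker. The sleep summary counts epochs
on the 30 s grid (0.5 min each); this short demonstration night happens to
contain no REM, so the REM latency is flagged undefined.

A full study — wake stimulation block, control night with masked LEDs,
experimental night, per-stage PSD40/SSVEPamp, sleep metrics, and the
hypothesis battery H1–H8 — runs with:

```r
bundle <- run_pipeline(default_run_config(seed = 1))
bundle$stats
```

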