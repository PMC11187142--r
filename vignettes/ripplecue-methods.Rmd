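---
title: "Methods: ripple-spindle coupling and cue-locked reactivation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple-spindle coupling and cue-locked reactivation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

During non-REM sleep, targeted memory reactivation (TMR) re-presents sound
cues that were paired with learning material before sleep. The working model
is that a cue triggers a cortical slow oscillation (SO)-spindle complex,
that hippocampal/MTL sharp-wave ripples (80-120 Hz, 25-300 ms) nest into the
spindle rhythm - preferentially toward the spindle *trough* - and that the
memory trace is reactivated precisely in these spindle-locked ripple windows.
`ripplecue` implements the full analysis chain needed to test that model on
epoched scalp or intracranial EEG: event detection, cross-frequency coupling,
circular statistics, multivariate decoding with temporal generalization, and
cluster-based permutation inference - plus a synthetic-data generator with
complete ground truth, so that every stage can be validated without access
to patient recordings.

## Pipeline overview

The TMR analysis (`run_tmr_analysis()`) executes, in dependency order:

1. **Time-frequency contrast.** Hanning-taper TFR (1-25 Hz, 5 cycles per
   frequency, 50 ms steps), z-scored across the whole epoch per trial,
   channel and frequency; learning-cue vs control-cue trials compared with a
   two-sample cluster permutation test. The significant positive
   (learning > control) cluster becomes the **SO-spindle cluster mask**; a
   rectangular fallback (12-16 Hz, 0.5-1.5 s) is used if no cluster
   survives.
2. **Median split.** Each learning trial is scored by its mean z-power over
   the mask; trials are split at the median into high and low SO-spindle
   power sets. Ties at the median go to the low set.
3. **Event detection.** Ripples on MTL contacts (80-120 Hz, 20 ms RMS window
   plus one smoothing pass of the same length, threshold mean + 2 SD over
   all TMR samples, duration 25-300 ms, at least 3 cycles in the raw
   signal); spindles on the cortical contact with the strongest 12-15 Hz
   power in the 0-1.5 s post-cue window (12-15 Hz, 200 ms RMS window,
   mean + 1.5 SD, duration 0.5-3 s). Peri-event ripple-rate histograms
   (50 ms bins) are built for the high and low split.
4. **Cross-frequency coupling.** Segments centered on MTL ripple peaks
   (qualifying = peak in the 0.7-1.4 s post-cue window and inside a detected
   spindle on the reference contact) feed a comodulogram: phase 4-20 Hz
   (full bandwidth 0.3 x f), amplitude 20-130 Hz (0.7 x f), Modulation Index
   with 18 phase bins, and a 100-repetition trial-shuffle surrogate null.
5. **Phase coupling.** The spindle-band (12-15 Hz) Hilbert phase of the
   reference contact is read out at every qualifying ripple peak; the
   circular mean and the V test against the trough (mu = +/- pi) quantify
   the preferred coupling phase. Phase 0 is the spindle peak throughout.
6. **Decoding.** Retrieval and TMR epochs are common-average referenced,
   whole-trial baselined, z-scored across trials per time point, projected
   on 30 principal components fitted to the *pooled* retrieval + TMR data,
   and smoothed with a 150 ms running average. A shrinkage-regularized LDA
   is trained per retrieval time point and applied (a) to every TMR time
   point in the high and the low SO-spindle split (their AUC difference is
   the split contrast) and (b) to TMR segments re-centered on spindle-locked
   ripple peaks, which are compared against a surrogate baseline built by
   re-centering on 100 sets of random non-ripple time points in the same
   0.7-1.4 s window.

The retrieval arm (`run_retrieval_analysis()`) runs 5-fold cross-validation
(repeated 5 times) of remembered-trial head-orientation decoding against
chance (0.5) with a cluster permutation test, and compares peri-event ripple
rates between remembered and not-remembered trials.

## Parameters that matter

| parameter | default | unit | note |
|---|---|---|---|
| ripple band / duration / threshold | 80-120, 0.025-0.300, mean + 2 SD | Hz, s | RMS window 20 ms, one extra smoothing pass |
| minimum ripple cycles | 3 | - | counted on the raw (demeaned) signal over the event extent |
| spindle band / duration / threshold | 12-15, 0.5-3, mean + 1.5 SD | Hz, s | stand-in detector; see Limitations |
| run merge gap | 20 (ripple), 50 (spindle) | ms | sub-threshold gaps shorter than this are bridged |
| TFR grid | 1-25 Hz, 50 ms | Hz, s | 5 cycles per frequency, Hanning taper |
| MI phase bins | 18 | - | 20 degrees each; MI = KL(P, uniform) / log 18 |
| comodulogram bandwidths | 0.3 x f (phase), 0.7 x f (amplitude) | - | full widths centered on f, clamped at 1 Hz |
| qualifying ripple window | 0.7-1.4 | s post-cue | window of preferred spindle-ripple interactions |
| PCA components | 30 | - | clamped to the channel count with a warning |
| smoothing window | 150 | ms | centered, shrinking at the edges |
| CV folds x repetitions | 5 x 5 | - | stratified, seeded |
| cluster permutations | 1000 | - | sample threshold p = 0.05, two-sided, Monte Carlo p = (b+1)/(n+1) |
| surrogate exclusion radius | 100 | ms | minimum distance of surrogate centers from any ripple peak |

Every default that the analysis literature fixes (bands, windows, thresholds,
counts) is kept at that value; the remaining knobs live in
`pipeline_config()` and `sim_params()`.

## The synthetic generator

`make_task_dataset()` emulates the statistical structure the analysis
assumes, not the biophysics:

* 1/f Gaussian background (slope 1, SD 10 uV) per trial and channel;
* retrieval trials carry a fixed class-specific channel template (unit RMS,
  scaled by `pattern_snr` = 1 x background SD under a Hann time envelope) in
  the 0.1-0.6 s window - remembered trials only, since decoding of forgotten
  material is the generative null;
* learning-cue TMR trials with the SO-spindle-ripple complex (half of them
  by default, the "reactivation" trials) receive a slow wave at 0.4 s, a
  1 s spindle burst (13.5 Hz, Tukey envelope) centered in 0.95-1.15 s on all
  cortical channels with a fixed amplitude gradient (so one contact is the
  strongest spindle site), and MTL ripple bursts (90 Hz, 100 ms, negative
  polarity at the peak, 4 x background SD) placed where the spindle phase
  equals a von Mises(mu = pi, kappa = 2) draw; the class template is
  injected for 300 ms centered on each ripple;
* control-cue trials and non-reactivation learning trials are background
  only;
* cues are spaced 5.5 +/- 0.2 s apart; epochs span -1 to 3 s at 1000 Hz.

One template per class is shared between retrieval and TMR (the premise of
cross-task classification). All draws come from one seeded generator with a
documented order, so a fixed seed reproduces the study bit-exactly.

**Waveform choices.** Ripples are Gaussian-windowed sinusoids - the simplest
waveform that satisfies the detector's duration and cycle criteria. Spindles
use a Tukey(0.5) envelope (flat central half) rather than a Gaussian: an RMS
detector with a 0.5 s minimum duration sees only the part of a burst that
stays above threshold, and a Gaussian envelope of realistic nominal duration
spends too little time there to be detectable as a spindle at all. The flat
plateau makes the nominal duration and the detectable duration agree, which
is what the duration criterion presumes about real spindles.

**What the generator does not emulate** - and hence what passing tests do
not show about real data: no biophysical coupling (events are injected, not
emergent), no artifacts or epileptiform activity (real-data users must
pre-clean), no REM or wake epochs, no inter-subject variability (one
"subject" per study), no volume conduction beyond the shared templates, and
ripple counts per trial are deterministic rather than overdispersed (the
per-trial dispersion of real ripple counts is unreported, so the generator
keeps it at the simplest choice of one ripple per reactivation trial).

## Statistical machinery

**Cluster permutation test.** Sample-level dependent t (against a chance
value or paired condition) or pooled-variance independent t (two groups),
thresholded two-sided at p = 0.05; clusters are contiguous runs (1D) or
4-connected regions (2D) per sign, scored by summed t. The null is the
maximum absolute cluster mass over sign flips (paired) or group-label
shuffles (two-sample); Monte Carlo p uses the +1 correction. Zero-variance
cells get t = 0 and are reported. The observed t map and cluster masses are
exactly invariant to unit ordering; the Monte Carlo p varies within sampling
error because the null draws attach to unit positions.

**V test.** V = n R cos(theta_bar - mu), u = V sqrt(2/n), upper-tail normal
p. Calibration on uniform angles (kappa = 0) is checked at n = 30 over 500
simulated samples.

**Modulation Index.** Empty phase bins contribute zero mass before
renormalization; an all-zero amplitude returns MI = 0 with a warning, and a
single-bin mass returns exactly 1. MI is computed on the concatenation of
event-locked segments (filtered per segment, so no cross-segment edge
artifacts). Surrogates permute the *trial* assignment of the amplitude
segments, exactly the shuffle quoted for the original analysis. On synthetic
single-ripple trials this null is conservative: every segment is centered on
its ripple, so the amplitude bump is time-locked in every segment and
shuffling preserves part of the coupling. The V test on ripple phases,
which does not suffer from this, carries the coupling inference in the
pipeline; the comodulogram's calibration is established separately on
segments whose coupling is carried by the oscillation itself
(`make_pac_segments()`), where the trial shuffle is exact. For the
uncoupled-noise calibration the observed *maximum* MI is compared against
the null distribution of the per-shuffle maximum (a max-statistic
correction); comparing the selected peak cell against its own cell-wise
null would be anti-conservative.

**Decoding.** AUC is the normalized Mann-Whitney statistic with midrank tie
handling, identical to the concordant-pair count. The LDA covariance is
shrunk toward its scaled identity with a Ledoit-Wolf intensity (`gamma =
"auto"`, configurable); at `gamma = 0` it matches classical LDA. Chance
calibration averages the time-mean AUC over five independent label shuffles
- a single shuffled labeling shared by all time points leaves the time-mean
AUC with substantial variance because time points are strongly dependent.

## Numerical choices and degenerate inputs

* Z-scoring uses the n-1 (sample) SD; zero-variance cells become 0 with a
  warning. Running averages use shrinking edge windows (output length =
  input length; constant input unchanged). Epochs lock to the nearest
  sample.
* Resampling is Fourier-domain (spectrum truncated at the new Nyquist, the
  ideal anti-alias filter); pass-band amplitudes of band-limited content are
  preserved exactly, at the price of mild wrap-around effects at recording
  edges. A polyphase resampler was measured to distort a 10 Hz sine by ~14%
  in amplitude, which is why it is not used.
* TFR output times whose 5-cycle window does not fit in the epoch are `NA`
  and excluded from averages; with 4 s epochs this applies to all of 1 Hz
  and the edges of low frequencies, matching the behavior of standard
  time-frequency tools at these settings.
* Cycle counting uses sign changes with a 10% amplitude gate (hysteresis)
  after demeaning. The detector counts cycles on the raw signal over the
  event extent - the criterion is meant to reject transients whose raw trace
  does not oscillate, and band-pass filtering would smear any sharp
  transient into apparent cycles. For isolated short segments a two-pass
  filter's edge transients would dominate, so `count_cycles()` demeans
  instead of filtering.
* The median split sends ties at the median to the low set; an all-equal
  score vector is an error.
* Circular means with a numerically zero resultant return `R = 0` with an
  undefined (`NA`) direction. Angles are kept in (-pi, pi], with -pi mapped
  to +pi so "the trough" has one representative.
* Antipodal trough convention: the V test is run against mu = pi; angles
  near -pi wrap to +pi first.

## Design choices where the design was open

* **Threshold scope for epoched detection** pools the RMS statistics over
  all trials of a channel ("across all data points"), then detects per
  trial. Per-trial thresholds were measured to inflate false alarms several-
  fold on trials without events.
* **Z-scoring order** for the cross-task analyses: each set (retrieval, TMR)
  is z-scored across its own trials before pooling for PCA. A flag is not
  exposed because the pooled-PCA step makes the two orders nearly
  equivalent on z-scored data.
* **Ripple peak convention**: the maximal *negative* band-filtered amplitude
  (`peak_sign = "negative"`, switchable to `"absolute"`), matching how
  ripple-locked averages are displayed in the field.
* **High/low split decoding** reuses the pooled PCA rather than refitting
  per split, matching the cross-classification setup.
* **Units for single-study cluster tests**: participants are unavailable in
  a single synthetic study, so the retrieval decoding test uses the
  fold x repetition AUC time courses as units and the ripple-rate and TFR
  contrasts use trials with the two-sample (label-shuffle) variant - the
  fixed-effects analog of the published contact-level analysis.
* **Correlation**: Spearman by default (`rank_correlation()`), Pearson
  available, since reported correlation statistics in this literature are
  typically rank-based.

## Problem sizes used by the validation suite

The packaged validation drivers (used by `tests/` and
`scripts/acceptance.R`) run at these sizes, chosen to give stable estimates
on a single CPU: detector recovery on 10 min of 8-channel 1000 Hz data with
50 injected ripples; comodulogram calibration on 50 uncoupled datasets of
10 x 1 s segments with 100 trial shuffles each; coupling-direction recovery
over 200 samples of 30 angles; V-test size over 500 samples; decoding chance
calibration on 100 trials x 8 channels at 200 Hz with 5 label shuffles;
cluster-test family-wise error over 500 AR(1) datasets (15 units x 100 time
points, 200 permutations); ripple-locked gain over 20 independent studies of
24 + 36 trials with 10 surrogate repetitions; and one full pipeline run on
the default 40 + 60-trial study with 500 permutations, 50 MI surrogates and
20 decoding surrogates.

## Known limitations

* The spindle detector is a documented stand-in (the source analyses do not
  specify one); its duration statistics must not be compared against
  published spindle durations.
* All inference on a single synthetic study is fixed-effects; group-level
  claims require multiple subjects/studies.
* The EDF writer quantizes to 16 bits (error bounded by one digital step)
  and requires integer sampling rates and whole-second durations.
* The generator's event amplitudes (3-4 x background SD) are at the
  conspicuous end of physiological reality; detector operating points on
  real data will be less favorable than the synthetic recovery rates.
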