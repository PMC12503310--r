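---
title: "Quantifying 60 Hz visual entrainment in EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 60 Hz visual entrainment in EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainEEG)
```

## The measurement problem

Flickering light at 60 Hz drives a steady-state visual evoked potential: a
narrowband EEG oscillation at the stimulation frequency. Quantifying it
faces three obstacles. The response is small (a microvolt or two) against a
1/f background tens of microvolts strong; the stimulation frequency sits
close to both the 50 Hz mains line and the upper edge of the conventional
0.5–80 Hz EEG band; and absolute spectral power differs across channels,
subjects and days for reasons unrelated to the stimulus. The pipeline
therefore measures *relative, baseline-normalized* quantities throughout:
band power as a fraction of broadband power, further divided by the same
fraction in a no-light baseline recorded minutes earlier in the same
session, and phase-locking matrices divided element-wise by their no-light
counterparts. Multiplicative per-channel gains cancel exactly in these
ratios (the package tests assert this scale invariance).

Each session has three segments — no light, constant light, flicker — so
that constant light serves as a control isolating the effect of flicker
from the effect of light per se. The stimulus runs at 59.6 Hz rather than a
nominal 60 Hz: a microcontroller can realize 16.778 ms periods exactly,
whereas 16.67 ms would accumulate rounding drift. All analysis bands are
chosen so that this fundamental lies comfortably inside.

## Preprocessing chain

Order matters and is fixed: 50 Hz notch → 0.5–80 Hz band-pass → common
average reference → sync-based segmentation → artifact masking. Filtering
precedes segmentation so that filter edge transients land in the no-light
head of the recording; estimation functions additionally trim 1 s from both
ends of every segment.

* **Notch.** A 2nd-order IIR notch with quality factor 35 (−3 dB width
  ≈ 1.4 Hz), applied forward and backward. The quality factor is not
  critical because the 49–51 Hz neighbourhood is excluded from every
  downstream integral.
* **Band-pass.** Butterworth coefficients of prototype order 2, applied
  bidirectionally (zero phase, effective order 4). A consequence worth
  stating plainly: with the upper edge at 80 Hz, an order-2 shoulder
  attenuates 60 Hz by about 11% per direction (bidirectional gain ≈ 0.89).
  This attenuation is identical in every segment of a session, so it cancels
  in the baseline normalization; the tests assert the filter's actual
  response rather than an idealized flat passband.
* **Average reference.** The cross-channel mean is subtracted per sample,
  over EEG channels only. Note that a component common to all channels
  (including a perfectly phase-aligned entrained response) is removed by
  construction; with physiologically distinct phases per channel the
  response survives mostly intact.
* **Segmentation.** A 100 ms trailing moving-maximum envelope of the sync
  trace, thresholded at half its dynamic range, bridges the flicker's
  off-phases. A trailing (rather than centered) window leaves light-on
  onsets in place: a clean step edge is recovered exactly, and flicker
  onsets within one envelope window. Segmentation is invariant to positive
  rescaling of the sync trace.
* **Artifact masking.** Non-overlapping 1 s windows in which any channel
  exceeds ±100 µV are masked; masked windows are skipped entirely by the
  Welch averager and dropped from the PLV sum (dropping, not interpolating:
  interpolated phase fabricates synchrony). A segment more than half masked
  raises a warning that propagates into the cohort report. This
  amplitude-threshold stage is a deliberately simple automated surrogate
  for manual artifact screening; ICA-based removal is treated as an
  external, pluggable preprocessing step outside this package's scope.

## Spectral quantities

The PSD estimator is an averaged periodogram: 4 s Hamming windows, 50%
overlap, per-window demeaning, one-sided density scaling. Four-second
windows give a 0.25 Hz grid — four grid points across the 1 Hz analysis
band — and roughly 29 averaging windows per minute of data, a sensible
variance/resolution compromise at these segment lengths. The full-segment
DFT periodogram serves as an independent oracle in the tests; the two agree
on stationary signals within 10%.

Band power uses the discrete rectangle rule: the sum of in-band grid-point
densities times the grid spacing, inclusive of both edges. With an
off-grid 59.6 Hz tone, the Hamming mainlobe places most of the tone's mass
on the 59.5 Hz grid point; a trapezoidal rule would half-weight that edge
point and systematically lose ~25% of the tone, so the rectangle convention
(the standard discrete band-power definition) is used instead.

The band fraction divides power in 59.5–60.5 Hz by power in 2–80 Hz with
49–51 Hz excised. The band contains the 59.6 Hz fundamental with margin on
both sides; its first harmonic (119.2 Hz) lies above the 80 Hz analysis
ceiling, which is why the entrained component is modelled and measured at
the fundamental only. Excluding 49–51 Hz makes the denominator independent
of the notch design. Both bands are configurable.

The STFT uses a 0.5 s Hamming window with a 0.25 s hop (frame count
`floor((n − window)/hop) + 1`, fractional hops rounded down per frame), and
temporal stability is summarized in consecutive 4-minute bins of the
stimulus segment, trailing partial bin dropped.

## Phase-locking

Synchrony at the stimulation frequency is the modulus of the mean complex
phase difference over samples. Phases come from the Hilbert analytic signal
of the 59.5–60.5 Hz zero-phase band-passed trace; the first and last second
are flagged as filter transients and excluded. The diagonal is computed
from the identically-zero self-difference and is therefore exactly 1, a
useful end-to-end sanity check. For pooled small-PLV estimation note the
estimator's positive bias: |mean| of K noisy unit phasors concentrates
around `sqrt(PLV² + 1/K)`; the recovery tests therefore pool phase series
across seeded replicates before taking the modulus rather than averaging
per-replicate moduli.

Dividing a condition's PLV matrix by the no-light matrix yields relative
synchrony; region-pair summaries average all cross-region channel pairs for
each unordered pair of distinct regions. Group summaries use off-diagonal
entries only.

## The synthetic-data generator

Each channel is the sum of four components, in microvolts at 250 Hz:

| parameter | default | meaning |
|---|---|---|
| `entrainmentAmplitudes` | 2 µV | per-channel amplitude of the stimulus-locked sinusoid (0 = sham) |
| `phaseOffsets` | evenly spaced | per-channel phase of that sinusoid |
| `jitterKappa` | 8 | von Mises concentration of phase jitter; `Inf` disables, 0 = uniform |
| `jitterKnotS` | 2 s | knot interval of the sample-and-hold jitter process |
| `backgroundExponent` | 1 | spectral slope of the 1/f^α background |
| `backgroundSd` | 10 µV | total SD of the colored background (band-limited 0.5 Hz–Nyquist) |
| `lineNoiseAmplitude` | 5 µV | 50 Hz sinusoid, random phase per channel |
| `whiteNoiseSd` | 1 µV | sensor noise |

The entrained component is `A_c sin(2π·59.6·t + φ_c + ψ_c(t))` with
`ψ_c` drawn independently per channel as iid von Mises(0, κ) values on a
knot grid and held constant between knots. Independence across channels
gives the closed-form expected PLV `(I₁(κ)/I₀(κ))²` for every pair, and the
expected band fraction follows from the configured amplitudes and the
analytic noise spectrum, including the sinc²-shaped broadening that the
knot process imposes on the incoherent part of the tone.

The knot interval deserves a note. The measurement filter (1 Hz-wide
Butterworth, bidirectional) has a ring time of roughly 0.45 s and smooths
the measured phase; jitter that varies on a similar timescale would be
partially averaged away and the measured PLV would sit far above the
marginal closed form. Conversely, very slow jitter leaves too few
independent phase draws per segment, inflating the modulus estimator's
small-sample bias. Two-second sample-and-hold knots keep the transition
regions a small fraction of the signal while providing ~30 independent
draws per minute; a prototype sweep over knot intervals during design
confirmed that this choice recovers the closed form within a few hundredths
across κ from 0.5 to 8. Phase interpolation between knots was rejected
because interpolated phases are less dispersed than the marginal
distribution, which provably breaks the closed form.

The sync trace encodes the light state as an analog 0–1 signal: zero during
no light, high during constant light, the square wave during flicker. A
0.2 s light-off switching gap is placed at the *end* of the constant-light
segment so that both light-on onsets are detectable by envelope
thresholding and coincide exactly with segment starts.

What the generator does *not* emulate, and what passing tests therefore do
not demonstrate about real data: non-stationary background (drowsiness,
alpha bursts), ocular/muscle artifacts with realistic morphology (the
artifact tests inject synthetic spikes), harmonic content of the
entrained response, volume-conduction correlations in the background noise,
electrode impedance drift, and day-over-day habituation as a generative
mechanism (habituation is *simulated* by assigning lower amplitudes and κ
to later days, with defaults chosen by inverting the closed-form expected
normalized power to the group-mean trajectory the pipeline is designed to
detect, about 2.8/2.4/1.5 across the three recording days).

## Statistical inference

The decision flow mirrors standard practice for these data: Shapiro–Wilk on
every cell; if any cell rejects normality at α = 0.05, the nonparametric
branch is taken (rank-sum for two groups, Kruskal–Wallis plus
Dunn–Bonferroni for more), otherwise the parametric branch.

Exactness switch points are explicit package decisions: the rank-sum test
uses the exact null distribution when the pooled sample is ≤ 12 without
ties, and the Kruskal–Wallis p value comes from exhaustive enumeration of
all distinct group assignments when pooled N ≤ 12 (ties allowed; the
tie-corrected H is evaluated on each assignment), falling back to the
χ²(k−1) approximation beyond. Enumeration is cheap at these sizes and
makes the tests verifiable against independent oracles to 10⁻¹⁰. Dunn's
z statistics use average ranks with the standard tie-corrected variance and
Bonferroni adjustment by the number of compared pairs. Fisher's exact test
follows the two-sided "no more probable than observed" convention. The
two-way ANOVA takes the Type-II path, which coincides with the classical
decomposition for balanced designs; a zero-variance response reports the
no-effect path (all SS = 0, p = 1) rather than NaN.

Two caveats are reported rather than silently resolved. First, pooling
channel-level (or channel-pair-level) observations across subjects treats
channels as independent replicates — pseudo-replication; a
`unit = "subject"` mode averaging within subject first is provided.
Second, the across-day comparisons use independent-sample Kruskal–Wallis
even though days are repeated measures on the same subjects; no
repeated-measures correction is invented because none is specified for
this design, and the limitation is stated here.

Cortisol analysis normalizes each subject's concentrations to day 1
(fold change), excluding subjects whose collection clock time drifts more
than 1 h from their day-1 sample, a guard against diurnal variation.
Side-effect events aggregate into weeks following the weekday session
calendar: days 1–5, 8–12, 15–19. Percent decreases round half away from
zero, matching how such percentages are conventionally reported.

## Numerical choices and degenerate inputs

* Segment intervals are half-open, 0-based samples; durations convert via
  `round(fs·t)`.
* PSD estimation requires ≥ 8 s of data and at least one artifact-free 4 s
  window; violations are errors naming the requirement, not silent NA.
* Narrowband filter designs are rejected when any pole radius reaches
  1 − 10⁻⁵: such filters ring for ~10⁵ samples under bidirectional
  application, longer than any session segment.
* A degenerate all-zero segment produces an explicit zero-total-power
  error in `bandFraction()`, and a zero baseline is an error in both
  normalizations (naming the channel pair for PLV).
* EDF export uses 1 s records with per-channel 16-bit physical scaling;
  round-trip error is bounded by the per-channel amplitude divided by
  32767. Text export carries full double precision to 10 significant
  digits.
* All randomness flows from a single integer seed per configuration;
  background and entrained draws consume the generator in a documented
  order, so identical configurations are bit-identical across platforms.

## Problem sizes in the test suite

The protocol durations (300/300/1200 s) are the simulator defaults, but the
suite runs on scaled sessions: 60 s segments for recovery tests (the length
at which the closed-form recovery tolerances are calibrated), 12–34 s
segments for I/O and orchestration tests, a 14-subject × 3-day cohort with
30/12/60 s segments for the end-to-end habituation pattern, and 2000
replicates per test for type-I-error calibration. Band-power recovery
compares per-channel estimates pooled over three seeded sessions against
the closed form (single-segment periodogram noise at 60 s is a few percent
SD, so pooling isolates the systematic component); PLV recovery pools
phase series over ten seeded sessions per κ before the modulus, for the
bias reason above.

## Known limitations

Beyond the generator's idealizations listed above: the pipeline analyses
the fundamental only (no harmonic or cross-frequency measures); PLV is
undirected synchrony, not connectivity; the artifact stage is
amplitude-only; the average reference is the only re-referencing scheme
offered; and the statistics deliberately replicate the source analysis
design, including its pooling caveats, rather than fitting mixed-effects
models.
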