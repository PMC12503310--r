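# entrainEEG

Analysis of flicker-induced 60 Hz neural entrainment in multichannel EEG.

Rhythmic visual stimulation drives a steady-state visual evoked potential
(SSVEP): the EEG develops a sustained oscillation at the flicker frequency.
`entrainEEG` implements a complete, tested pipeline for quantifying this
entrainment in sessions that follow a three-segment protocol — a no-light
baseline, a constant-light control, and a flickering-light stimulus phase
driven by a 59.6 Hz square wave (period 16.778 ms, 50% duty cycle) — recorded
from 8 scalp electrodes (10–20 system) at 250 Hz plus a photoresistor sync
channel.

It is intended for researchers analysing such sessions (or planning them) and
ships a first-class synthetic-data module, so every stage is testable without
any recordings.

## What it computes

**Normalized entrainment power.** Per channel, the Welch power spectral
density of each segment, the band fraction

```
F = ∫[59.5, 60.5] S(f) df  /  ∫[2, 80]\[49, 51] S(f) df
```

and the baseline-normalized power `F_stimulus / F_no-light`. Temporal
dynamics come from a Hamming STFT (0.5 s window, 0.25 s hop) and consecutive
4-minute bins; spatial summaries average channels into Frontal (Fp1, Fp2),
Central (C3, C4), Temporal (T5, T6) and Occipital (O1, O2) regions.

**Phase synchrony.** Signals are band-passed 59.5–60.5 Hz with a zero-phase
2nd-order Butterworth filter, phases are extracted with the Hilbert
transform, and for every channel pair the phase-locking value

```
PLV_ij = | (1/N) Σ_n exp( j (φ_i(n) − φ_j(n)) ) |
```

is computed and normalized to the no-light matrix.

**Group statistics.** A Shapiro–Wilk normality gate; Wilcoxon rank-sum for
active-vs-sham contrasts; Kruskal–Wallis across days (exact permutation
enumeration for pooled N ≤ 12, chi-square beyond) with Dunn–Bonferroni post
hoc; Fisher's exact test for proportions; two-way ANOVA (group × time) for
biomarkers; plus cortisol fold-change normalization to day 1 (with a 1 h
collection-time window) and weekly side-effect tallies.

**Synthetic sessions with ground truth.** The simulator superimposes a
stimulus-locked sinusoid (per-channel amplitude and phase, von Mises phase
jitter on 2 s sample-and-hold knots) on 1/f background, 50 Hz line noise and
sensor noise, and returns closed-form expectations: the in-band power
fraction and the pairwise PLV `(I₁(κ)/I₀(κ))²`. Recovery of both is part of
the test suite.

## Worked example

```r
library(entrainEEG)

cfg  <- simulationConfig(segmentDurations = c(no_light = 60,
          constant_light = 20, stimulus = 60), seed = 7)
sess <- simulateSession(cfg)          # active session, kappa = 8, 2 uV
pp   <- preprocessPipeline(sess$recording)

stim <- segmentSamples(pp$recording, pp$segments, "stimulus",  mask = pp$mask)
base <- segmentSamples(pp$recording, pp$segments, "no_light",  mask = pp$mask)
fS   <- bandFraction(estimatePsd(stim$samples, 250, mask = stim$mask))
fB   <- bandFraction(estimatePsd(base$samples, 250, mask = base$mask))
round(normalizeToBaseline(fS, fB), 2)
#>  Fp1  Fp2   C3   C4   T5   T6   O1   O2
#> 6.28 5.97 7.74 6.48 6.31 6.40 6.40 5.76

plv <- computePlv(instantaneousPhase(narrowbandFilter(stim$samples, 250)),
                  mask = stim$mask, condition = "stimulus", day = 1)
plv
#> PLVMatrix [stimulus, day 1]: 8 channels, mean off-diagonal 0.778 (N=14000)
```

The normalized power of ~6 says the stimulus segment carries about six times
more relative 60 Hz power than the resting baseline on every channel — a
strong entrainment response. The mean off-diagonal PLV of 0.78 sits close to
the generator's closed-form expectation of 0.875 for κ = 8, pulled down
slightly by in-band background noise at this 2 µV amplitude.

Cohort-level runs (`simulateCohort()` → `runCohortAnalysis()` →
`emitReport()`) produce tidy TSV tables and a JSON summary; a thin
command-line wrapper with verbs `config`, `simulate`, `preprocess`,
`entrain`, `plv`, `stats`, `report` and `run-all` is installed at
`exec/entrain-cli.R`.

## Documentation

The methods vignette (`vignettes/entrainment-pipeline.Rmd`) describes the
models, the generator's assumptions and its relation to real EEG, all
tunable parameters with defaults and units, and the numerical choices made
throughout the pipeline.
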