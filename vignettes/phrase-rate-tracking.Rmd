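---
title: "Methods: frequency-tagged analysis of phrase-rate neural tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged analysis of phrase-rate neural tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrasetrack)
```

## The paradigm

In a frequency-tagging design for speech, monosyllabic words are played
isochronously at 2 Hz (500 ms per word), so that two-word phrases — when
the listener can form them — occur at exactly 1 Hz. Because the acoustic
signal is modulated only at the word rate, any 1-Hz component of the EEG
must be endogenous: it reflects the listener grouping words into larger
units. The package implements the full analysis chain for a six-condition
design that crosses **structural regularity** (whether adjacent words form
grammatical phrases) with **sequential regularity** (whether a part of
speech repeats every phrase):

```{r}
condition_designs()
```

Three conditions are grammatical (`V-N`, `V-Adv`, `V-Adv-alt`); within
them, `V-N` vs. `V-Adv` contrasts complement vs. adjunct attachment, and
`V-Adv` vs. `V-Adv-alt` contrasts consistent vs. alternating head
position. `N-R` repeats a noun every phrase without forming phrases;
`R-R` and `V-V` have no 1-Hz regularity of any kind.

## Tracking statistics

Epochs (trials × channels × samples) are transformed with a plain
whole-epoch DFT — no taper, no zero padding — so the frequency resolution
is exactly `1/epoch_duration` (1/22 Hz for canonical 22-s epochs), which
places the 1-Hz and 2-Hz tags precisely on bins 22 and 44. A taper would
smear the tags across bins and is deliberately not offered.

Two statistics quantify tracking at a frequency $f$:

* **Evoked power**: trials are averaged in the time domain *first*, then
  transformed; power is the squared magnitude of the average's
  coefficients. Averaging first cancels activity that is not phase-locked
  to the stimulus (it decays as $1/k$ in the trial count $k$, a property
  the test suite verifies).
* **ITPC** (inter-trial phase coherence), from the phase angles
  $\theta_k$ of the per-trial coefficients, magnitudes discarded. Two
  conventions are implemented and linked by an exact identity:
  $$R(f) = \frac{1}{k}\Big[\big(\sum_k \cos\theta_k\big)^2 +
  \big(\sum_k \sin\theta_k\big)^2\Big] = k \cdot
  \Big(\frac{1}{k}\big|\sum_k e^{i\theta_k}\big|\Big)^2 .$$
  The left form ranges over $[0, k]$; the right (squared mean resultant
  length) is built on the familiar $[0,1]$-bounded coherence. The
  pipeline default is the `normalized` convention (mean resultant
  length), whose values are directly comparable across trial counts and
  whose chance level for uniform phases is $\sqrt{\pi/(4k)}$ (about 0.18
  at $k = 24$); the `printed_formula` convention is retained as an
  option. Which scale a given published figure uses can be ambiguous, so
  the package never converts silently — the convention is carried in the
  result object.

## Peak inference

A spectral "peak" is a bin exceeding its neighborhood. For each
condition, per-subject channel-averaged spectra supply one target-bin
value and one neighbor-average value per subject; the group labels
(target/neighbor) are permuted freely over the merged sample, and the
one-sided p-value for $\Delta = \bar{x}_{target} - \bar{x}_{neighbor}$
is $(1 + \#\{\Delta^* \ge \Delta\})/(1 + n_{perm})$. The `+1` smoothing
avoids zero p-values at finite permutation counts. Neighbor rules differ
by statistic: power uses the three bins to the *left* of the target
(respecting the $1/f$ decay of EEG power — right neighbors would bias
the baseline down), while ITPC, which has no such trend, uses three bins
on each side. Averaging the neighbor bins before permutation keeps the
two groups the same size; the alternative of entering each neighbor bin
as its own observation is deliberately not the default.

Downstream inference mirrors standard practice: paired t-tests between
conditions with Benjamini–Hochberg FDR correction over the family of
pairs actually tested; a classical 2×2 within-subject ANOVA in which each
effect is tested against its own effect-by-subject interaction
($F = MS_{effect}/MS_{effect \times subject}$, df 1 and $n-1$); and
post-hoc contrasts on estimated marginal means (equal to cell means in
this balanced design) using paired SEs and Tukey adjustment via the
studentized-range distribution over the four cell means. With a
two-cell family the adjustment collapses to the unadjusted paired t — a
reduction the tests check against the closed form.

The transitional-probability control asks whether condition differences
in 1-Hz ITPC are explained by bigram statistics
$P(w_2 \mid w_1) = P(w_1 w_2)/P(w_1\#)$. Observations enter at the
subject × condition level (with 20 subjects and 3 grammatical
conditions, 60 observations and a slope df of 58); the alternative
reading of one observation per trial is inconsistent with that df and
is not implemented.

## The synthetic cohort generator

Every stage is exercised against synthetic EEG with known ground truth.
Each trial is

$$x(t) = a_w \sin(2\pi \cdot 2t + \phi_w) +
         a_p \sin(2\pi \cdot 1 (t - \tau) + \phi_p) + \epsilon(t),$$

with trial phases $\phi$ drawn from a von Mises distribution (mean 0,
concentration $\kappa$), a Gaussian latency shift $\tau$ applied to the
phrase component only in the alternating-head condition (modelling the
temporal jitter that inconsistent head position induces in the
endogenous phrase-level response), and $1/f^{\alpha}$ Gaussian noise
synthesized in the frequency domain with random phases. All channels
carry the same expected signal scaled by a fixed random topography
vector; per-subject lognormal amplitude multipliers add between-subject
variability while keeping amplitudes positive.

Defaults (all tunable through `eeg_sim_params()`):

| parameter | default | meaning |
|---|---|---|
| `word_rate`, `phrase_rate` | 2, 1 Hz | stimulation rates |
| `amp_word` | 1 µV | word-rate amplitude, all conditions |
| `amp_phrase` | 1 / 0.75 / 0.55 / 0.5 / 0 / 0 µV | phrase-rate amplitude for V-N / V-Adv / V-Adv-alt / N-R / R-R / V-V |
| `phase_concentration` | 6 | von Mises $\kappa$ of trial phases |
| `latency_jitter_sd` | 0.06 s | phrase-latency SD, alternating head only |
| `noise_exponent`, `noise_scale` | 1, 12 µV | $1/f^{\alpha}$ slope and RMS |
| `n_trials`, `n_channels`, `fs` | 24, 59, 500 | epoch geometry |
| `epoch_duration` | 22 s | analysis window |
| `n_subjects`, `between_subject_sd` | 20, 0.25 | cohort size and dispersion |

The amplitude pattern encodes the hybrid hypothesis — a phrase-rate
response wherever *any* 1-Hz regularity exists (structural or
sequential), graded by attachment type and head-position consistency,
and absent in `R-R`/`V-V`. The SNR operating point (signal amplitudes
about 4–8% of the broadband noise RMS) was fixed once by a
parameter-recovery calibration: cohorts generated at these defaults must
yield significant 1-Hz ITPC peaks in exactly the four regular
conditions in at least 80% of cohort seeds and reproduce the amplitude
ordering in the recovered ITPC means in at least 90% (the acceptance
tests verify both). At much higher SNR
the ITPC saturates and amplitude ordering becomes invisible; at much
lower SNR the `N-R` peak disappears. The chosen point keeps recovered
ITPC values in the 0.15–0.6 range typical of strong steady-state
paradigms.

What the generator does *not* emulate: realistic scalp topographies (no
forward model, no dipoles), ocular or muscle artifacts, trial rejection
imbalance across conditions, harmonics of the response rates, or
non-stationary noise. Tests passing on this synthetic cohort therefore
certify the *statistical machinery* — calibration, power, ordering
recovery, exactness of the algebra — not the package's behavior on any
particular real recording.

## Numerical choices and degenerate inputs

* **Determinism**: every stochastic routine takes an explicit seed and
  restores the caller's RNG state; identical seeds give bit-identical
  output, and `run_pipeline()` derives all stage seeds from the single
  config seed, making reports byte-reproducible.
* **Filtering**: the 0.3–25 Hz bandpass is realized as a zero-phase
  (forward–backward) cascade of a 3rd-order high-pass and 4th-order
  low-pass Butterworth filter. The contract — ≥ 95% amplitude retention
  on $[2 \cdot low, high/2]$, ≥ 90% attenuation at $2 \cdot high$, DC
  removed, no group delay — is asserted on synthetic tones rather than
  assumed from the design.
* **Token normalization**: shorter tokens are zero-padded symmetrically
  (odd remainder: the extra sample goes at the end); longer tokens are
  truncated symmetrically. The onset/offset ramp is a quarter-sine
  ($\sin(\pi t / 2T_r)$) over the first and last 10% by default, with a
  raised-cosine alternative.
* **Envelope extraction** fixes the order half-wave rectification →
  analytic-signal magnitude (FFT method) → anti-aliased polyphase
  decimation to 200 samples/s → DFT. The resampling FIR leaves sub-1%
  edge transients, which is why envelope assertions compare peaks
  against neighbor means rather than against exact zeros.
* **Undefined phases**: a zero-magnitude Fourier coefficient has no
  phase; ITPC treats it as 0 and counts the occurrence in a warning
  field rather than failing.
* **Degenerate statistics**: constant paired differences yield $t = 0,
  p = 1$ (all equal) or $t = \pm\infty, p = 0$; a zero effect sum of
  squares yields $F = 0$ even when the error term is also zero.
* **Permutation edge cases**: a target bin without the required
  neighbors (spectrum edge) is an error, not a silent truncation.

## Problem sizes in the test suite

Unit tests run on reduced geometries (2 channels, 4–8-s epochs at
100 samples/s) because every contract checked there — bin alignment,
convention identities, oracle agreement — is scale-invariant. The two
simulation studies use single-channel cohorts of 20 subjects × 24
trials: the type-I calibration runs 200 null cohorts at 250 samples/s
(the null distribution of the peak test does not depend on the sampling
rate), and the parameter-recovery study runs 50 six-condition cohorts at
the full 500 samples/s defaults, with 1,000 permutations per test.
These sizes keep the whole suite within a coffee break on one CPU while
leaving the Monte-Carlo margins far from the acceptance thresholds.

## Known limitations

* ICA-based ocular artifact removal is a documented no-op hook; the
  synthetic cohorts contain no such artifacts, and real data should be
  cleaned upstream.
* Channel-wise statistics are exported, but no scalp-map rendering or
  cluster-based spatial inference is provided.
* The EDF and BrainVision readers cover the common single-rate,
  int16/float32 cases used for data exchange, not the formats' every
  corner (no EDF+ annotations; multiplexed orientation only).
* The bigram corpus generator produces an abstract Zipf–Markov word
  chain; it reproduces the *statistical shape* of corpus counts, not any
  natural language's lexicon.
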