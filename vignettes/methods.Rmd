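---
title: "Methods: spectral, coupling and behavioral analysis of extinction-session LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, coupling and behavioral analysis of extinction-session LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thetagamma)
```

## Scope and model

The package analyses single-channel mPFC LFP recorded during tone
fear-extinction sessions: a 3-min baseline, then 40 conditioned-stimulus
tones of 30 s separated by 5 s inter-trial intervals (ITIs), ending with a
tone (39 separating ITIs; a trailing ITI is available as an option for
symmetric designs). Four families of read-outs are produced per animal:
relative band power (theta 4–12 Hz, low gamma 30–45 Hz, high gamma
55–90 Hz, gamma 30–90 Hz), theta-phase→gamma-amplitude coupling, freezing
behavior, and open-field locomotion; a statistics harness compares groups
of animals.

No public raw recordings exist for this paradigm at desk scale, so
validation is simulation-based: the generator in `generate_lfp()` /
`generate_cohort()` is a first-class, tested component whose ground truth
anchors every claim the test suite makes.

## Preprocessing

The conditioning chain is band-pass → notch → decimation.

* **Band-pass**: fifth-order Butterworth, 1–120 Hz, applied zero-phase
  (forward–backward). The literature source of the parameters does not
  state the application direction; zero phase is the defensible default
  because the coupling analysis downstream depends on undistorted phase.
* **Notch**: a second-order IIR notch at 50 Hz. The stated "width 0.1 Hz"
  is mapped to the −3 dB bandwidth of the biquad, i.e. quality factor
  Q = 500; that bandwidth is the only free parameter of the mapping.
* **Decimation**: integer-factor subsampling to 1 kHz. If the trace's
  provenance does not already record a low-pass covering the new Nyquist
  (the 120 Hz band-pass does), an explicit zero-phase Butterworth
  anti-alias low-pass at 0.4 × target rate is inserted, so stages used
  à la carte can never alias silently. Non-integer factors are refused —
  arbitrary-rate resampling is out of scope.

**Numerical realization.** At 30 kHz the normalized lower band edge is
6.7 × 10⁻⁵, where a Butterworth design expressed as a single transfer
function is numerically unstable in double precision. All IIR filters are
therefore designed from the analog prototype and factored into cascaded
second-order sections (biquads), applied by a small compiled kernel
(direct form II transposed). The section design reproduces the reference
transfer-function designer to ~1e-10 where the latter is well conditioned;
the test suite asserts this.

**Edge handling.** Zero-phase filtering uses reflective padding of about
three times the filter's impulse-response time constant. The reflection
type is chosen per filter: even (mirror) reflection for the band-pass and
anti-alias stages, because the alternative point-symmetric reflection
shifts the padding's local mean by 2·x(end) and the 1 Hz high-pass rings on
that step; point-symmetric (odd) reflection for the notch, because the
mirror's slope kink injects energy inside the extremely narrow (0.1 Hz)
rejection band. A Q = 500 notch has a ~3 s impulse response, so a boundary
transient of that scale at the trace edges is unavoidable for any causal
implementation; steady-state attenuation (which is what matters for
continuous recordings many minutes long) is evaluated on the trace
interior.

## Welch spectra and normalization

`welch_psd()` averages Hann-tapered, mean-detrended, 50 %-overlapping
segment periodograms into a one-sided density (µV²/Hz). The defaults —
2048-sample segments with 1024-point overlap — give ≈ 0.488 Hz resolution
at 1 kHz and at least 3 segments in a 5 s ITI, which is why ITIs are
analysed per interval and then averaged. "2048 FFTs" in the source
description is read as the segment length; with the stated 1024
overlapping points that is the natural 50 % overlap reading.

Two normalization schemes exist because the paradigm uses two references:

* `normalize_whole_spectrum()` divides by the mean raw power over
  1–120 Hz; the normalized spectrum then averages exactly 1 over that band
  and all derived band powers are invariant to rescaling the raw signal
  (amplifier gain drops out).
* `normalize_to_baseline()` divides by the scalar mean of the same
  animal's baseline-period PSD over 0–120 Hz, computed with identical
  Welch parameters. The DC bin is included as printed in the source
  convention; a switch excludes it (a documented deviation) — after
  band-pass and notch conditioning the DC bin is essentially zero, so the
  choice is immaterial in practice.

Band power is the **mean** (not the integral) of normalized PSD bins with
`low ≤ f ≤ high`, inclusive on both edges; means make bands of unequal
width comparable as "relative power", and the integral is available as an
option. The 45–55 Hz gap between the gamma sub-bands keeps 50 Hz line
leakage out of both by construction.

Per-condition spectra (`psd_by_label()`) average per-interval PSDs rather
than concatenating intervals: concatenation would let Welch segments
straddle interval boundaries and mix non-adjacent data. Concatenation
remains available (`mode = "concatenate"`) since the source convention is
unstated; the two agree to leading order on stationary signals.

## Phase–amplitude coupling

Phase and envelope are obtained from zero-phase FIR band-pass filtering
("FIT filter" in the source is read as FIR) followed by the FFT analytic
signal. The FIR is a Hamming-windowed sinc with transition bandwidth 25 %
of the lower band edge (≈ 3300 taps for theta at 1 kHz) — linear phase,
compensated exactly after filtering, so the phase estimate carries no
filter delay. The phase convention is cosine: phase 0 at the oscillation
peak, values in (−π, π].

The coupling metric is not stated in the source beyond "Hilbert
transform", so the package adopts the standard entropy-based (Tort)
modulation index over 18 phase bins: the bin-mean envelope profile is
normalized to a distribution and its KL divergence from uniform, scaled by
log(18), gives MI ∈ [0, 1]. It is bounded, exactly invariant to envelope
rescaling, and zero iff the profile is uniform. The preferred phase is the
amplitude-weighted circular mean. Empty phase bins (impossible in practice
with minutes of data) are dropped with a warning.

Per-condition coupling (`pac_by_label()`) extracts phase and envelope once
on the whole trace and then pools the samples of all same-label intervals.
This is deliberate: a 5 s ITI is shorter than the theta FIR itself, so
per-interval filtering is not meaningful, and whole-trace filtering leaves
no interval-boundary transients to trim. The tone/ITI coupling ratio is
MI(tone)/MI(ITI); an ITI index of exactly zero yields an explicit
"undefined" error rather than infinity.

## Session structure and behavior

Interval boundaries map to samples half-open, `[start, end)`, with
`floor((end − start) · rate)` samples per interval, so adjacent tone/ITI
segments never share a sample. Stages are hard-coded for the 40-trial
protocol (1–13 early, 14–26 intermediate, 27–39 late, trial 40 and its ITI
excluded); other trial counts fall back to thirds with the remainder
excluded and a warning, since that is a generalization the protocol itself
does not define.

Freezing: a frame is immobile iff its motion index is **strictly below**
the threshold (18 a.u.) — the boundary value counts as motion, a
deterministic tie-break the upstream scoring software does not document —
and a maximal immobile run of at least 30 frames (1 s at 30 fps) is
freezing. Runs are evaluated on the uncut trace, so a bout spanning a tone
onset keeps its full length and its frames are attributed frame-by-frame
to their intervals. Block summaries average 5 consecutive trials (8 blocks
for 40 trials).

Open field: the center is the concentric square of 900 cm² in the 50 cm
arena; the periphery is defined as arena minus center (1600 cm²), a
deliberate deviation from the printed "outer area of 2500 cm²", which is
the whole arena and cannot be a disjoint outer zone. Fractions of time in
center and periphery therefore sum to one by construction.

## Statistics

Two-group comparisons reproduce the conventional gate: Shapiro–Wilk on
each group at α = 0.05 (the gate level is unstated in the source; 0.05 is
the convention), then Student's t (variance-equality F test passes) /
Welch's t (it fails) / Mann–Whitney U (normality fails), all two-tailed.
Degenerate zero-variance groups route nonparametric. Animals — not trials —
are the experimental unit: trial-level values are averaged per animal
before group tests. Factorial designs use two-way ANOVA with pooled-MSE
pairwise contrasts and the Šidák adjustment `1 − (1 − p)^m` (the post-hoc
named in the source figure conventions; Tukey/LSD alternation there has no
stated selection rule, so the package exposes the choice and defaults to
Šidák). Linear mixed models are delegated to `lme4` behind a thin
group-effect LRT contract and are intentionally not re-implemented.

## The synthetic-data generator

The generator emulates what the analysis assumes about the recordings:

| component | default | rationale |
|---|---|---|
| sampling rate | 30 kHz (configurable) | acquisition-system rate |
| aperiodic background | 1/f² shape, SD 30 µV | typical LFP aperiodic exponent ~2 |
| theta | 8 Hz, 50 µV | mid-band theta, dominant rodent mPFC rhythm |
| low / high gamma carriers | 40 Hz @ 10 µV, 70 Hz @ 8 µV | gamma an order of magnitude below theta |
| coupling depth m | 0.5, preferred phase 0 | moderate coupling at the theta peak |
| line noise | 50 Hz, 5 µV | mains contamination for the notch to remove |
| white noise | SD 10 µV | sensor/amplifier floor |
| between-animal CV | 0.15 | inter-individual spread of absolute LFP power |

The gamma envelope in an interval of condition *c* is
`base · gain(c) · (1 + m(c)·cos(φ_θ − φ₀)) / (1 + m(c))`; the `(1+m)`
normalization keeps mean gamma amplitude independent of coupling depth, so
band-power and coupling effects can be varied orthogonally — a property
the monotonicity tests rely on. The 1/f background is generated by
frequency-domain shaping of white noise, which hits the target exponent
exactly (the suite checks the log-log PSD slope over 5–100 Hz recovers −α
within ±0.3). Per-animal seeds are derived deterministically from the
master seed, so cohorts are bit-reproducible while animals remain
independent streams.

Between-animal variability (lognormal, mean-1, CV 0.15 by default,
applied to the theta/gamma/aperiodic amplitudes of each simulated animal)
matters for realism of the group statistics: with statistically identical
animals, a group test at N = 5 resolves arbitrarily small systematic
biases — including the ~1–2 % shift that baseline normalization leaks into
*all* bands when one band is attenuated, because the attenuated band also
contributes to the shared 0–120 Hz denominator. With realistic
inter-animal spread that leak is far below detectability and the
no-effect band's false-positive rate sits at the nominal α, which is
exactly the dissociation the effect-recovery report
(`power_recovery_report()`) quantifies.

Scripted freezing constructs one contiguous sub-threshold bout per
interval of `round(target · n_frames)` frames (bouts shorter than the
30-frame minimum are dropped to zero, since the scorer could never count
them), so the scorer's expected output equals the target exactly when the
target is representable. The motion index itself is an abstract
non-negative process (supra-threshold exponential background); the
proprietary "linear method" of the upstream video software is not modeled.

### What the simulations do not capture

No spiking, no biophysical network dynamics, no non-stationary aperiodic
drift, no movement or chewing artifacts, no electrode drift, and gamma
occurs as continuous amplitude-modulated carriers rather than discrete
bursts. Passing tests therefore demonstrate that the *pipeline* recovers
known spectral/coupling/behavioral structure at realistic SNR and cohort
sizes — not that any biological claim about real recordings is reproduced.

## Problem sizes and tolerances

The validation suite runs scaled-down but structurally faithful sessions:
cohort replications use 20 s baselines and 8 × 30 s tones with 5 s ITIs at
N = 5 per group, generated directly at the 1 kHz analysis rate (all
simulated components lie below 120 Hz, so generating at 30 kHz and
decimating is mathematically equivalent and only slower); coupling
recovery uses 120 s traces over coupling depths {0, 0.25, 0.5, 0.75, 1}
with 20 seeds per depth. Exact identities (normalization means, Šidák
closed form, Welch vs enumerated periodograms, freezing scorer vs
run-length enumeration) are asserted at 1e-9–1e-12; estimator checks use
tolerances derived from their sampling variability (e.g. the type-I rate
of the gated test within two binomial standard errors of α over 1000 null
replicates).

## Known limitations

* The notch's edge transient (~3 s at Q = 500) contaminates trace ends;
  recordings shorter than ~10 s should not rely on the notch.
* Baseline normalization couples bands through the shared denominator (see
  above); whole-spectrum normalization does the same within a session.
  This is inherent to the published normalization schemes, not an
  implementation artifact.
* `welch_psd()` refuses traces shorter than one segment rather than
  shrinking the segment, so 2 s of data cannot be analysed at the default
  resolution — by design, to keep resolutions comparable across
  conditions.
* The comodulogram (arbitrary frequency-pair sweep) and cross-regional
  coupling are out of scope; only the three canonical bands are analysed.
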