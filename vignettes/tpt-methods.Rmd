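---
title: "Models and methods behind the tpt toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tpt toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpt)
```

This vignette documents the scientific choices inside `tpt`: the
stimulus model and its slider-to-acoustics calibration, the measurement
recipes, the scoring pipeline, the psychometric estimators, and the
synthetic-respondent model — including the places where the instrument's
published description left a genuine design decision to us, and what
passing the package's tests does and does not establish about real
listeners.

## Stimulus model

Each stimulus is a complex tone of eight equal-amplitude sinusoidal
partials at integer multiples 1–8 of the fundamental. Three slider
dimensions (0–100) control its timbre:

**Envelope.** Attack and decay times follow an exponential link with
base 1.03, affinely calibrated to the instrument's printed range:
attack(s) = A·1.03ˢ + B with A = 286/(1.03¹⁰⁰ − 1) and B = 5 − A, so
attack runs 5 → 291 ms; decay is calibrated the same way from 50 → 5 ms.
A raw power law 1.03ˢ cannot hit both endpoints (1.03¹⁰⁰ ≈ 19.2 ≠
291/5), so the affine calibration is the only member of the stated
family consistent with the stated range; it keeps the log-scaled
perceptual spacing of the base while pinning the endpoints. The
amplitude envelope itself is a linear attack ramp, full-level sustain,
and linear decay ramp. Ramps are open-ended (first/last samples are not
exactly zero) so tone onsets remain detectable and trial gaps keep their
nominal length.

**Spectral flux.** The partials at base multiples 3, 4, 5 and 6 are
detuned linearly with the slider to (3.3, 3.7, 5.2, 5.8) at slider 100.
Multiples 3 and 5 rise while 4 and 6 fall, so neighbouring partials
converge and beat. The scalar summary is β, the mean absolute deviation
of the four ratios from their integer bases: β = 0.25·(s/100). The
instrument's prose indexes harmonics from f0×2 ("4th–7th harmonics"),
which conflicts with its own printed baseline ratios of 3.0–6.0; we
follow the printed ratios, i.e. base multiples 3–6.

**Spectral centroid.** A bandpass filter with centre
600 + 400·(s/100)² Hz and fixed Q = centre/bandwidth = 1.8. The
quadratic link is adopted over a "logarithmic" reading because it alone
places the reference 700 Hz at slider 50. The filter is a second-order
constant-peak-gain resonator (α = sin ω₀ / 2Q); at 44.1 kHz the bilinear
warping error is negligible and the rendered −3 dB ratio measures 1.803
(the acceptance script recomputes this). The filter is applied before
the envelope so it cannot smear the attack.

Trials repeat the tone three times. The 800 ms repetition interval is
read as a silent gap from tone offset to the next onset (onset-to-onset
would overlap for long tones); it is configurable.

Defaults the published description does not fix, chosen once: equal
partial amplitudes; 700 ms tone duration; 44.1 kHz sample rate; pitch
set G3 and A#4 endpoints (12-TET, A4 = 440) with interior pitches C4,
E4, G4 — the instrument names only the endpoints, and "two octaves from
G3 to A#4" is musically inconsistent, so the interior pitches are an
explicit configurable choice.

## Measurement oracle

`measured_spectral_centroid` is the amplitude-weighted mean frequency of
the magnitude spectrum over the central half of the signal, with a
5-term flat-top window and FFT length ≥ 2¹⁵ (sub-2 Hz bins at 44.1 kHz).
`count_spectral_peaks` counts merged local maxima above a relative
threshold (default 5 % of the global maximum).

`measured_attack_time` takes the magnitude of the FFT-based analytic
signal, smooths it with a 5 ms moving average (killing harmonic-rate
ripple), and reports the time from the 1 % to the 99 % crossing of the
peak. One caveat discovered while validating the recipe: detuned
partials superimpose beating on the envelope at periods comparable to
the attack times themselves (tens of milliseconds), which no envelope
follower can separate from the ramp. The attack dimension is therefore
verified on in-phase stimuli (`flux_slider = 0`) — the factorial design
any acoustician would use — and agrees with the link values within 10 %
for attacks ≥ 20 ms (within ~2 % above 80 ms).

`envelope_fluctuation` quantifies beating as a band-limited coefficient
of variation: the RMS of envelope-spectrum components between 3 Hz and
0.75·f0, relative to the mean envelope. The band keeps inter-partial
beats (whose rates fall below f0 as detuning grows) and excludes the
harmonic ripple every complex tone carries. The index rises from ≈0 at
slider 0 to ≈0.12 at slider 100 across the pitch set; it is not finely
monotone near the top of the scale because at slider 100 the deviations
(±0.3, ±0.3, ±0.2, ±0.2) become commensurate and some beat components
merge — a property of the stimulus itself, not of the measure.

## Protocol and scoring

A full session is three blocks (envelope, flux, centroid), each with one
unscored training item, five match trials covering all five parameter
sets, and ten memory trials covering them twice — 45 scored items.
Presentation order is a pure function of the seed; item identities are
stable across seeds. The five parameter sets place targets at slider
values {10, 30, 50, 70, 90}, crossed with the five pitches through a
5×5 Latin square; the published per-set values live in an unavailable
appendix, so these defaults are synthetic and fully configurable. The
default (untouched) slider position is 50. The short version keeps only
match trials and drops the envelope and flux items whose targets sit at
the default position (distance 0 from an unmoved slider, hence no
discriminatory power) — 13 items, split 4/4/5.

Scoring: raw score = |target − final slider|, with unmoved sliders
scored at the default position rather than treated as missing. Items
with strictly more than 30 % unmoved observations are excluded. Each
retained item gets five interior boundaries at the type-1
(inverse-empirical-CDF) quantiles j/6 of its distance distribution —
rank-based, no interpolation, so occupancies are equal to within ties —
and distances map to scores 6 (best) down to 1. Observations tied with
a boundary fall in the better bin: deterministic and consistently in
the participant's favour. Boundaries persist as JSON so retest data is
scored against the original test's bins; a version tag prevents
applying a short-session bin table to a full session.

## Psychometric estimators

α is the classical Cronbach form. ω-total comes from a one-factor
minimum-residual fit: (Σλ)² / ((Σλ)² + Σψ); the instrument's final
model is a single factor, so the hierarchical generalization is out of
scope. The minres extraction optimizes uniquenesses by L-BFGS-B,
obtaining loadings from the leading eigenvectors of R − diag(ψ); a
uniqueness pinned at the lower bound raises a Heywood warning. Tests
verify the zero-gradient condition of the residual objective at the
solution and parameter recovery on synthetic factor models; `factanal`
(maximum likelihood) is used only as an independent cross-check, never
as the implementation.

Factor counts come from Kaiser's criterion (eigenvalues > 1) and
parallel analysis with 100 resamples of uncorrelated normal data and
the 95th-percentile criterion, seeded — common defaults, since the
source gives no settings. Solutions with more than one factor are
varimax-rotated. Model fit is summarized by RMSEA and BIC computed from
the normal-theory ML discrepancy evaluated at the minres solution with
a Bartlett-style multiplier (n − 1 − (2p+5)/6 − 2m/3) and
df = ((p−m)² − (p+m))/2; published human-sample fit values are not
reproduction targets, and the code comments state the formulas used.

Test–retest agreement uses the single-measure two-way random
absolute-agreement ICC(A,1) = (MSR − MSE)/(MSR + MSE + 2(MSC − MSE)/n),
reported with df = n − 1 (consistent with "ICC(24)" at n = 25);
absolute agreement penalizes systematic shifts that a consistency ICC
would ignore. Validity tables use tie-corrected Spearman correlations
with Benjamini–Hochberg step-up applied over the whole table as a
single family; constant columns are excluded from the family and
reported.

## Synthetic respondents

The simulator exists so the scoring and psychometric machinery can be
exercised end to end; it is an artifact model, never a claim about
human cognition. A respondent with latent ability a (standard normal
across a cohort) answers an item with final slider = target +
Normal(0, σ_dim · e^(−κa)), clipped to [0, 100]; with probability
p_stick the slider stays at the default. Noise acts on the slider scale
because responses and scoring both live there and the perceptual
mapping is unknown; the multiplicative e^(−κa) form keeps the sd
positive and the score–ability relation monotone. Memory trials
multiply the sd by `memory_multiplier` ≥ 1, reflecting that a single
playback degrades reproduction accuracy; memory items report exactly
one stimulus playback.

Cohort defaults, fixed once: n = 95 respondents (the scale of the
instrument's validation sample), σ_dim = 15 slider units for all three
dimensions, κ = 1, memory multiplier 1.5, p_stick = 0.05. Fifteen
slider units is a plausible mid-scale reproduction error for an
untrained listener (raw errors of 10–25 units), κ = 1 gives roughly a
3:1 noise ratio across ±1 SD of ability, and 5 % stick keeps all items
below the 30 % exclusion threshold while still exercising the unmoved
rule. Under these conditions a seeded cohort yields a single factor by
both Kaiser and parallel analysis, an ability–score Spearman
correlation above 0.5, and higher memory than match error in every
subtask. Retest simulations redraw the noise with the same abilities.

What the simulator does not emulate: learning and fatigue across
blocks, dimension-specific perceptual scales (noise is homoscedastic on
the slider), intentional near-target non-movements, or playback-count
strategies. Passing tests therefore demonstrate that the pipeline's
algorithms are correct and internally consistent — not that the
instrument's human-sample statistics would be reproduced, which depend
on its participants.

## Numerical and testing notes

All synthesis is deterministic; every stochastic step (session order,
cohorts, parallel analysis) is seeded explicitly. Problem sizes in the
test suite — cohorts of 20–95 (one 500-respondent null check),
5000-observation factor-recovery sets, 200-replicate ICC Monte Carlo —
were chosen as the smallest sizes at which the checked quantities are
stable at the stated tolerances. Degenerate inputs fail loudly:
constant distance distributions cannot be binned, zero total-score
variance has no α, zero between-subject variance has no ICC, singular
correlation matrices have no Bartlett statistic.
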