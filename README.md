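# tpt — a headless toolkit for the Timbre Perception Test

Timbre is the perceptual attribute that distinguishes sounds of equal
pitch, loudness and duration. The Timbre Perception Test (TPT) measures
individual differences in timbre perception with a method-of-adjustment
paradigm: the listener hears a complex-tone stimulus and moves a slider
(0–100) to make a reproduction tone match it along one of three timbre
dimensions —

- **amplitude envelope** (attack/decay times),
- **spectral flux** (detuning of partials from integer harmonic ratios,
  which produces beating), and
- **spectral centroid** (the "brightness" set by a bandpass filter's
  centre frequency).

Accuracy is the absolute slider distance |target − response|, converted
into equal-frequency bin scores (6 = best, 1 = worst bin).

This package re-implements the whole instrument as scriptable code, with
no GUI and no human participants required:

- **Synthesis** — eight equal-amplitude partials at f0 × {1..8}, with the
  partials at base multiples 3–6 detuned by the flux slider; calibrated
  link functions map sliders to acoustics (attack 5–291 ms and decay
  50–5 ms on a base-1.03 exponential; flux ratios 3.0–3.3, 4.0–3.7,
  5.0–5.2, 6.0–5.8 linearly; filter centre 600 + 400·(s/100)² Hz at
  fixed Q = 1.8). Trials repeat the tone three times with 800 ms gaps;
  WAV in/out.
- **Measurement oracle** — spectral centroid, attack time, spectral peak
  counting and an envelope-beating index, to verify rendered audio
  against the intended parameters.
- **Protocol** — full sessions (3 blocks × 5 match + 10 memory items +
  training = 45 scored items) and the short match-only version
  (13 items); CSV response tables.
- **Scoring** — absolute distances, the >30 %-unmoved item-exclusion
  rule, six equal-frequency bins per item (type-1 quantiles), and
  persisted bin boundaries so retest data is scored against the original
  test's bins.
- **Psychometrics** — Cronbach's α, McDonald's ω-total, two-way random
  absolute-agreement ICC(A,1), KMO, Bartlett's sphericity test,
  minimum-residual EFA with Kaiser and parallel-analysis factor counts,
  and Spearman correlation tables with Benjamini–Hochberg correction.
- **Simulator** — synthetic respondents with latent ability: responses
  are target + Normal(0, σ·e^(−κ·ability)) on the slider scale, noisier
  on single-playback memory trials, with a small probability of leaving
  the slider untouched.

## Worked example

```r
library(tpt)

spec <- stimulus_spec("C4", envelope_slider = 20, flux_slider = 60,
                      centroid_slider = 80)
tone <- synthesize_tone(spec)
measure_audio(tone)
#> Measured: centroid 1102.8 Hz, attack 108.1 ms, 8 spectral peaks,
#>           envelope CV 0.270

session <- build_full_session(seed = 1)
session
#> TPT session (full): 48 items (45 scored)
#>            match memory
#>   centroid     5     10
#>   envelope     5     10
#>   flux         5     10

sim <- simulate_cohort(cohort_spec(n_respondents = 95, seed = 7), session)
scored <- score_responses(sim$responses, session)
scored$report
#> Score report: 95 respondents, 4275 scored responses
#>   mean overall score 3.61 (range 1.91-5.69)

rs <- scored$report$respondent_scores
vars <- rs[, c("envelope_match", "flux_match", "centroid_match",
               "envelope_memory", "flux_memory", "centroid_memory")]
efa_minres(vars, seed = 11)
#> Minres EFA: 1 factor(s), 95 observations
#>   Kaiser suggests 1, parallel analysis 1
#>   KMO 0.93; Bartlett chi2(15) = 535.64, p = 1.61e-104
#>   variance explained 77%; RMSEA 0.000; BIC -35.7
```

The 8 spectral peaks confirm the eight-oscillator structure; the
measured centroid sits above the 856 Hz filter centre because the
Q = 1.8 passband is broad relative to the partial spacing. The simulated
cohort is driven by a single latent ability, and the factor analysis
recovers exactly that: one factor by both Kaiser's criterion and
parallel analysis. Aggregate bin scores average 3.61 on the 1–6 scale,
close to the 3.5 midpoint that equal-frequency binning forces for a
cohort scored against its own bin boundaries.

A command-line dispatcher over the same functions ships in
`inst/cli/tpt.R` (`render`, `render-trial`, `session`, `simulate`,
`score`, `psych`, `verify`).

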