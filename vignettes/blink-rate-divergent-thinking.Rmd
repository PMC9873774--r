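---
title: "Eye-blink rate, divergent thinking, and curvilinear mediation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye-blink rate, divergent thinking, and curvilinear mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkdt)
```

## The scientific problem

The spontaneous eye-blink rate (sEBR) — how often a person blinks per
minute while resting with eyes open — is widely used as a cheap,
non-invasive proxy of striatal dopamine function. Dopamine in turn is
implicated in divergent thinking: the ability to generate many,
varied, and original ideas, classically measured with the Alternative
Uses Task (AUT), in which participants list unusual uses for everyday
objects (a brick, a hat) under time pressure.

The empirical picture this package operationalises is an *inverted-U*:
intermediate blink rates (hence, putatively, intermediate dopamine
levels) are associated with the highest flexibility — the number of
distinct conceptual categories a person's ideas draw from — while both
low and high rates are associated with less flexible ideation.
Originality, rated by expert judges, relates *linearly* to
flexibility. Putting the two together yields a curvilinear mediation
hypothesis: blink rate influences originality *through* flexibility,
so the strength of that indirect influence depends on where on the
inverted-U a person sits.

`blinkdt` implements the complete analysis chain: blink detection from
frontal resting EEG, AUT scoring, inverted-U hierarchical and robust
regressions, and curvilinear mediation with bootstrap confidence
intervals — together with a synthetic-data generator that produces
inputs with *known* ground truth, so every stage can be validated
end to end without access to raw participant data.

## Blink detection

Blinks dominate frontal EEG channels (Fpz, Fz, Fp1, Fp2, F3, F4, FC3,
FC4) as large, roughly triangular ("tent"-shaped) deflections of the
order of 100 µV against a ~15 µV background. Detection proceeds in
four steps:

1. **Band-pass filtering**, 1–20 Hz, 4th-order Butterworth applied
   forward–backward (zero phase). Channels are demeaned before
   filtering so a DC offset cannot leak in as an edge transient; a
   consequence is that detection is exactly invariant to constant
   offsets in the raw signal.
2. **Candidate frames.** Candidate events are maximal runs where the
   filtered signal exceeds its overall mean by 1.5 standard deviations
   (both computed over the whole segment). Runs whose above-threshold
   duration does not exceed 50 ms are discarded — this is the step that
   removes brief noise excursions and small rapid eye movements. Each
   surviving run is then extended outward to the surrounding sub-mean
   samples, so that the *full* waveform base, not only its tip,
   defines the frame used for scoring. Frames closer than 50 ms are
   pruned keeping the larger amplitude (minimal inter-blink interval).
3. **Shape scoring.** Each frame receives a *tent correlation*
   (Pearson correlation with a two-piece linear tent anchored at the
   frame's onset, peak and offset; an exact triangular waveform scores
   1.0) and a *positive amplitude–velocity ratio*,
   pAVR = 100 · peak amplitude / maximum rising-limb velocity
   (units s⁻¹), with the peak measured above a local baseline taken as
   the mean of the 100 ms windows flanking the frame. Blinks rise over
   ~100 ms or more and score pAVR ≈ 10–15; saccades rise in ~20 ms and
   score pAVR ≈ 2. Acceptance requires tent correlation > 0.90 and
   pAVR ≥ 3; both thresholds are exposed as arguments.
4. **Channel selection.** Detection runs on every available frontal
   channel; the best channel is the one with the most accepted events
   (ties broken by higher median tent correlation), and the blink rate
   — 60 · count / duration — is computed from that channel only.

Two boundary behaviours are worth stating explicitly. First, the pAVR
floor of 3 is mathematically equivalent to requiring an effective rise
time of at least 30 ms; events with faster rises are classified as
saccades *by construction*, so very short tents (≲ 80 ms total width,
whose peaks are additionally attenuated by the 20 Hz low-pass edge) sit
on the saccade side of the boundary and are not recoverable. Recovery
is exact, and tested to be exact, for noiseless tents of physiological
width (150–400 ms). Second, the exceedance threshold is relative to
whole-segment statistics, so it adapts to the recording's own blink
density and noise level; in a segment that is almost all blinks the
threshold rises and short tents lose above-threshold duration.

## The synthetic EEG generator

`simulate_eeg()` builds a samples × channels matrix containing, at
each requested blink time, an additive piecewise-linear tent (linear
rise over `rise_ms`, default 120 ms, to the apex, default 100 units;
linear fall over `fall_ms`, default 180 ms), scaled per channel by a
frontal gradient (prefrontal 1.0, frontal 0.7, fronto-central 0.45),
plus optional saccade surrogates and white Gaussian noise (default SD
15, i.e. apex SNR ≈ 6.7). The tent is piecewise linear *on purpose*:
it makes the detector's tent-correlation criterion exactly satisfiable,
giving the test suite an exact-match case rather than only a
statistical one. The saccade surrogate is a 20 ms ramp to 0.4 × the
blink amplitude, an 80 ms plateau, and a 20 ms ramp down — long enough
to survive the duration rule, so that its rejection genuinely
exercises the pAVR criterion rather than an earlier filter.

What the generator does *not* emulate: real EEG rhythms (alpha/beta
oscillations), eyelid kinematics, electrode drift or artifacts other
than the embedded events. Background noise is white. Passing detection
tests on this generator therefore demonstrates that the detector
implements its stated criteria correctly — not that those criteria are
sufficient for every real recording.

## AUT scoring

Responses arrive in long format (participant, object, response text,
conceptual category, two judge ratings on a 1–5 originality scale).

- **Normalization** lowercases, strips filler phrases ("used for",
  articles, etc. — shipped as an editable plain-text list), unifies
  regular singular/plural forms, and collapses whitespace. Responses
  that normalize to the empty string are invalid and excluded from
  fluency. Equivalence after normalization is exact string match; the
  rule lists are configuration, so curators can extend them
  reproducibly rather than matching ad hoc.
- **Fluency** is the count of valid responses.
- **Flexibility** is the mean, over the study's objects, of the number
  of distinct categories used per object (0 for an unattempted
  object); this preserves the bound flexibility ≤ fluency / n_objects.
- **FB (frequency-based) originality** of a response is its statistical
  infrequency: 1 minus its relative frequency among all responses for
  that object across the sample (8 occurrences among 20 → 0.60). The
  participant score is the *pooled* mean over the participant's
  responses — pooling over responses rather than averaging object
  means is a deliberate choice where either reading is defensible, and
  it weights objects by how much the participant produced.
- **RB (rater-based) originality** of an idea is the mean of the two
  judges' ratings (an optional consensus column overrides the mean,
  mirroring consensus resolution of large discrepancies); the
  participant score is the mean over ideas.
- **Inter-rater reliability** is ICC(2,k): two-way random effects,
  absolute agreement, average measures, computed from the two-way mean
  squares and labelled in the output, since "the ICC" is ambiguous
  across variants.

The response simulator ties each participant's response counts to a
latent fluency multiplier, draws category counts per object that track
latent flexibility, samples response texts from a Zipf-weighted
per-object vocabulary (so common and rare responses coexist and FB
originality has spread), and generates the two ratings as a shared
latent idea quality plus independent judge noise. The judge-noise SD
is derived from the target ICC through the ICC(2,2) closed form
σ²ₑ = k·σ²_q·(1 − ρ)/ρ using the realised quality variance, which makes
the calibration tight (±0.05 at ~1700 ideas). Ratings are *clipped* to
[1, 5] but kept continuous: rounding to integers would inject
unmodelled variance into that calibration; the small clipping bias is
accepted and kept small by centring quality at 3.

## Association models

For each AUT index, `hierarchical_quadratic_fit()` fits the index on
sEBR (step 1) and on sEBR + sEBR² (step 2), reporting raw and
standardized coefficients, R² per step and ΔR² (non-negative for OLS
by construction), and flagging observations with |standardized
residual| > 3. `robust_quadratic_fit()` repeats the structure with
MM-estimation (S-estimate of scale, redescending bisquare M-step, 95%
Gaussian efficiency); its R² analogue is weight-based and labelled as
such, and the S-stage's subsampling RNG is pinned internally (with the
caller's RNG state restored) so results are reproducible. An
inverted-U is a significant *negative* step-2 squared term.

`required_sample_size()` reproduces the fixed-model regression power
computation: the smallest N whose noncentral-F power — noncentrality
λ = f²·N, numerator df for the tested effect, denominator df
N − p − 1 — reaches the target. With the conventional medium effect
f² = 0.15, α = 0.05, three predictors and a single-coefficient test
(numerator df = 1) the answer is N = 55. Whether such a power analysis
tests one coefficient or the full model R² is often left unstated in
applied reports; both are available via `numerator_df`, with the
single-coefficient reading as the default.

## Curvilinear mediation

With predictor X (sEBR), mediator M (flexibility) and outcome Y
(originality), the model is

- M = i_M + a₁X + a₂X² + e_M,
- Y = i_Y + bM + c₁X + c₂X² + e_Y,

fitted by OLS. When the predictor-to-mediator path is quadratic the
indirect effect is no longer a single number: its strength at
predictor value x is the *instantaneous indirect effect*

θ(x) = (a₁ + 2a₂x) · b,

the derivative of the fitted mediator curve times the
mediator-to-outcome slope. θ is exactly linear in x with slope 2a₂b,
and collapses to the classical product a₁b when a₂ = 0. θ is evaluated
at low / moderate / high predictor values, by default mean ± 1 SD of
the sample (sample SD, n − 1 denominator) — a rule consistent with
equally spaced conventional reporting points — with explicit override
supported. Squaring uses the raw predictor by default; a centring flag
exists, and θ at raw predictor values is invariant under it (asserted
in the tests).

Confidence intervals come from a case-resampling bootstrap:
participants are resampled with replacement (default 5000 times), the
two path models refitted per resample, θ evaluated at the original
sample's points, and percentile intervals taken at the requested
level. Percentile intervals were chosen over BCa as the simplest
variant to verify; case resampling (not residual resampling) matches
the individual-level data structure. Resamples with rank-deficient
designs are redrawn and counted. All stochastic outputs are
bit-reproducible under the spec's seed.

### Calibration and a known limitation

The test suite checks interval behaviour by simulation at deliberately
chosen sizes: coverage of the 95% interval at the moderate point is
95% ± 3 points over 200 replicates (n = 200, 1000 resamples per
replicate), and under an inverted-U effect at n = 73 the qualitative
pattern — interval excluding zero at low and moderate predictor
values, including zero at high values where the mediator curve is flat
— obtains in the majority of replicates.

Under a *null* b = 0 with a strong a-path, however, the percentile
interval at the moderate point excludes zero in about 8% of replicates
rather than 5% (n = 200, 500 replicates). This is a property of the
method, not of this implementation: per-replicate decisions agree 99%
with an independent implementation built on `boot::boot()`, and the
excess traces to the bootstrap distribution underestimating the
sampling SD by ~5% together with the excess kurtosis of a product
statistic. Mild liberality of percentile intervals for indirect
effects in the one-path-null regime is well documented in the
mediation literature; users wanting strict type-I control at the cost
of power should interpret marginal intervals cautiously.

## The population generator and its defaults

`simulate_participants()` draws X from a normal truncated below at 0.5
blinks/min with mean 10.76 and SD 6.05 — chosen so that the
conventional low/moderate/high reporting points fall at 4.71, 10.76
and 16.81 blinks/min, a realistic resting-blink-rate spread — and
generates M and Y from the structural equations above. Default paths
place the apex of the mediator curve one SD above the mean predictor
(a₁ = 0.1345, a₂ = −0.004), with b = 1.57, a weaker quadratic direct
path (c₁ = 0.02, c₂ = −0.001), and residual SDs 0.55 (M) and 0.5 (Y);
this yields a quadratic R² around 0.2–0.3 for the mediator model, a
strong linear flexibility–originality relation, and a θ profile that
is clearly positive at low/moderate predictor values and ≈ 0 at high
values. These defaults are the package's reference conditions and are
not re-tuned per analysis.

## Numerical choices and degenerate inputs

- Constant (zero-variance) channels yield zero blink candidates, not
  errors; constant predictors raise collinearity errors in regression;
  constant outcomes give exactly-zero robust slopes; zero-variance
  rating matrices make the ICC undefined (reported as NA with a
  warning); zero-variance predictors make the evaluation points a
  degenerate triple with a warning.
- Candidate frames of fewer than 3 samples are marked degenerate and
  rejected rather than scored.
- A jointly noiseless mediation data set (σ_M = 0) makes the outcome
  design rank-deficient — the mediator is then an exact function of
  the predictor — and `fit_paths()` raises an informative error; the
  identifiable exact-recovery cases are tested instead.
- Problem sizes in the test suite (e.g. 200–500 simulation replicates,
  1000 bootstrap resamples, n = 1000 samples for significance-rate
  checks) were chosen as the smallest sizes at which the binomial or
  Monte-Carlo error of the checked quantity is comfortably below the
  asserted tolerance.

## Orchestration

`run_full_analysis()` runs the whole chain from one nested
configuration (or YAML file): simulate participants → synthesise one
EEG segment per participant with the blink count implied by that
participant's rate and recover sEBR by detection → simulate and score
AUT responses → correlations and hierarchical/robust regressions →
curvilinear mediation. Every stage receives a seed derived
deterministically from the global seed; every intermediate table is
written under the output directory; and a manifest records the
configuration, seeds and md5 hashes of all artifacts, so a rerun with
the same configuration is verifiably identical. A thin command-line
wrapper (`inst/cli/blinkdt`) exposes the individual stages as
subcommands for shell use.
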