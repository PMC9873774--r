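# blinkdt

Spontaneous eye-blink rate (sEBR) — how often someone blinks per minute
during eyes-open rest — is a non-invasive proxy of striatal dopamine
function, and dopamine is implicated in divergent thinking: the
capacity to generate many, varied, original ideas. `blinkdt` is an R
package for researchers studying that link. It implements the full
analysis chain from raw signals to inference:

- **Blink detection** from frontal resting EEG (Fpz, Fz, Fp1, Fp2, F3,
  F4, FC3, FC4): 1–20 Hz zero-phase band-pass, amplitude-threshold
  candidate frames (mean + 1.5 SD, > 50 ms), acceptance by
  tent-shape correlation (> 0.90) and positive amplitude–velocity
  ratio (pAVR ≥ 3, rejecting saccades), best-channel selection, and
  the blinks-per-minute rate.
- **Alternative Uses Task (AUT) scoring**: response-text
  normalization, fluency, flexibility (distinct conceptual categories
  per object), frequency-based originality (statistical infrequency,
  1 − relative frequency within object), rater-based originality
  (mean of two judges on a 1–5 scale), and inter-rater reliability as
  ICC(2,k).
- **Association models**: Pearson correlation matrices, hierarchical
  linear → quadratic regressions of each AUT index on sEBR (an
  inverted-U is a significant negative squared term), robust MM
  counterparts, and noncentral-F power / sample-size computation.
- **Curvilinear mediation**: with mediator model
  M = i_M + a₁X + a₂X² + e and outcome model
  Y = i_Y + bM + c₁X + c₂X² + e, the instantaneous indirect effect

  &nbsp;&nbsp;&nbsp;&nbsp;**θ(x) = (a₁ + 2a₂x) · b**

  is evaluated at low / moderate / high predictor values
  (mean ± 1 SD) with percentile confidence intervals from a
  case-resampling bootstrap (default 5000 resamples).
- **Synthetic-data generators** for every input: EEG-like recordings
  with tent-shaped blinks, saccade surrogates and known ground truth;
  participant tables with a known inverted-U mediation structure; and
  long-format AUT responses with judge ratings calibrated to a target
  ICC. These make the whole pipeline testable without access to raw
  participant data.

## Worked example

```r
library(blinkdt)

# 1. a population of 73 participants with a known inverted-U structure
pop <- simulate_participants(population_sim_config(n_participants = 73, seed = 7))

# 2. a 3-minute resting EEG segment for the first participant, with the
#    blink count implied by that participant's rate, then detection
set.seed(7)
times <- spaced_event_times(round(pop$sebr[1] * 3), 180, 0.35)
sim <- simulate_eeg(eeg_sim_config(duration = 180, blink_times = times, seed = 7))
detect_blinks(sim$recording)
#> <blink_series> 74 blinks on Fp2 over 180.0 s  (24.67 blinks/min)
round(pop$sebr[1], 2)   # ground truth for this participant
#> [1] 24.6
```

The detector recovers the implanted rate (24.67 vs 24.6 blinks/min).
Next, AUT responses and their four indices:

```r
responses <- simulate_aut_responses(pop, response_sim_config(seed = 7))
scored <- score_aut(responses)
scored$icc
#> ICC = 0.885  [ICC(2,k) two-way random, absolute agreement, average measures; 1658 items x 2 raters]
head(scored$participants, 3)
#>   participant_id fluency flexibility fb_originality rb_originality
#> 1           P001      33         3.0      0.8989461       2.292649
#> 2           P002      16         2.6      0.9291876       2.635672
#> 3           P003      19         2.8      0.9277250       2.635819
```

The judge simulation was calibrated to ICC 0.88 and the computed
ICC(2,k) over all 1658 ideas is 0.885. The inverted-U regression of
flexibility on sEBR:

```r
hierarchical_quadratic_fit(pop$sebr, pop$flexibility)
#> Hierarchical fit (OLS), n = 73
#> Step 1 (linear):
#>          term estimate      se      t         p
#> 1 (Intercept)  2.73042 0.16574 16.474 5.864e-26
#> 2           x  0.03341 0.01225  2.726 8.058e-03
#> Step 2 (quadratic):
#>          term  estimate       se      t         p
#> 1 (Intercept)  2.137256 0.276439  7.731 5.704e-11
#> 2           x  0.143557 0.043578  3.294 1.550e-03
#> 3      I(x^2) -0.004167 0.001587 -2.625 1.063e-02
#> R2: step1 = 0.0948, step2 = 0.1759, delta = 0.0811
```

Adding the squared term raises R² by 0.081 and its coefficient is
negative and significant — the inverted-U. Finally, the curvilinear
mediation of originality by flexibility:

```r
med <- bootstrap_mediation(as_mediation_data(pop, y = "originality"),
                           mediation_spec(n_boot = 5000, seed = 7))
med
#> Curvilinear mediation (n = 73, 5000 bootstrap resamples)
#> paths: a1 = 0.1436, a2 = -0.00417, b = 1.4416, c1 = -0.0089, c2 = -0.00004
#>                x   theta ci_lower ci_upper
#> low       6.6537  0.1270   0.0590   0.1965
#> moderate 12.3058  0.0591   0.0209   0.0951
#> high     17.9578 -0.0088  -0.0796   0.0339
```

θ(x) = (a₁ + 2a₂x)·b is positive with intervals excluding zero at low
and moderate blink rates — at those levels, higher sEBR predicts more
original ideas *through* greater flexibility — while at high blink
rates, past the apex of the inverted-U, the indirect effect vanishes.
The design sample-size computation behind studies of this kind:

```r
required_sample_size(f2 = 0.15, alpha = 0.05, power = 0.80, n_predictors = 3)
#> [1] 55
```

`run_full_analysis()` chains all stages (simulate → detect → score →
analyze → mediate) from a single YAML configuration with per-stage
seeds, writing every intermediate table plus a hash manifest; see
`inst/extdata/demo_config.yaml` and the methods vignette in
`vignettes/` for the model details, parameter defaults, and known
limitations.

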