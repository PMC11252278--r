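# audiencesync

Quantifying interpersonal physiological synchrony in audiences that share a
stimulus — and linking each listener's synchrony to affect, personality and
experience.

When many people listen to the same concert, their heart rate (HR),
heart-rate variability (HRV, RMSSD), respiration rate (RR) and phasic skin
conductance (SCR) can become coordinated without any social interaction.
`audiencesync` implements the full analysis chain for such *induction
synchrony*:

* **SUSY, the dyadic surrogate-synchrony statistic.** Two feature series
  are cut into 30-s segments; within each segment, Pearson
  cross-correlations are computed at all lags up to ±5 s (the ten-second
  cross-correlation range *L*), Fisher-Z transformed
  (`z = arctanh(r)`), and averaged within and then across segments into a
  signed synchrony score *Z* (in-phase *Z* > 0, anti-phase *Z* < 0). A
  null distribution is built by re-pairing the segment sequence with random
  derangements (no segment meets itself), giving surrogate scores
  *Z*surr and the effect size

  ```
  ES = (Z − mean(Zsurr)) / sd(Zsurr)
  ```

* **Audience aggregation.** All N(N−1)/2 dyads of an audience; each
  participant's *synchrony contribution* (the mean of their N−1 dyadic
  *Z* values, with a participant-level surrogate distribution and ES); the
  group-level presence test (paired t-test of *Z* vs *Z*surr across
  participants); per-piece slicing; and a cross-channel composite.
* **Feature derivation** from raw-level signals: HR from inter-beat
  intervals, RMSSD-HRV in sliding windows, RR/RESP from a respiration-belt
  waveform via peak detection, SCR via moving-median tonic removal.
* **Mixed-model inference**: random-intercept models
  (`contribution ~ covariates + (1 | concert)`, REML) with within-concert
  centering where appropriate, pre/post affect effect sizes
  (`(pre − post)/SD_pre`) and paired t-tests, and post-hoc piece contrasts
  with Holm correction.
* **A synthetic concert simulator** with known ground truth (shared latent
  driver, per-participant coupling and lags, an uncoupled breathing
  channel, planted covariate effects), so the entire pipeline runs and is
  tested without any external data.

## Worked example

Simulate two small concerts, compute audience synchrony for heart rate and
breathing behaviour, and regress the HR contributions on two personality
traits:

```r
library(audiencesync)

cfg <- simulation_config(n_concerts = 2, n_participants_per_concert = 12,
                         duration_s = 600, seed = 42)
ds <- simulate_concerts(cfg)
sy <- run_synchrony(ds, susy_params(rng_seed = 42),
                    channels = c("HR", "RESP"), scopes = "concert")
print(sy$presence, digits = 3)
#>   channel   scope  mean_Z mean_Zsurr t_statistic  p_value mean_ES  n
#> 1      HR concert 0.09210  -0.004472       13.47 2.12e-12   7.184 24
#> 2    RESP concert 0.00219   0.000481        2.56 1.76e-02   0.622 24

d <- merge(sy$contributions[sy$contributions$channel == "HR", ], ds$survey,
           by = c("concert_id", "participant_id"))
fit_random_intercept_model(d, "ES_contribution",
                           c("Openness", "Extraversion"), "concert_id",
                           center_predictors = FALSE)
#> Mixed model for ES_contribution (n = 24)
#>          term estimate    se     t        p
#>   (Intercept)    7.015 1.814  3.87 0.000894
#>      Openness    1.357 0.417  3.25 0.003800
#>  Extraversion   -1.199 0.336 -3.57 0.001810
#> Random intercept: 27.3% of variance; model r2 = 57.0%
```

Reading the output: the coupled HR channel synchronizes massively above its
surrogate null (mean contribution ES ≈ 7, p ≈ 10⁻¹²), while breathing
behaviour — simulated as independent per-participant oscillators — shows an
order-of-magnitude weaker signal whose test fluctuates around the 5% level
at this toy audience size. The planted personality effects (Openness
positive, Extraversion negative) are recovered with the correct signs.

At study scale (the simulator's defaults: 11 concerts × 60 participants)
the same pipeline is exercised by the test suite: coupled channels are
significant at p < 0.01 in every seed, RESP stays null, and all planted
covariate signs are recovered.

A thin command-line wrapper is included at `inst/cli/audiencesync.R`:

```sh
Rscript inst/cli/audiencesync.R simulate --seed 7 --out data/
Rscript inst/cli/audiencesync.R analyze --data data/ --out results/
```

which writes `dyads.csv`, `contributions.csv`, `presence_tests.csv`,
`models.csv` and a markdown report (including a planted-effect recovery
section when ground truth is present).

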