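---
title: "Surrogate-tested physiological synchrony in audiences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-tested physiological synchrony in audiences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(audiencesync)
```

## The problem

When an audience listens to the same music, individual listeners' autonomic
physiology — heart rate (HR), heart-rate variability (HRV), respiration rate
(RR), breathing behaviour (RESP), and phasic skin conductance (SCR) — can
become coordinated even though the listeners do not interact. Because social
interaction is absent, such coordination must be *induction synchrony*:
quasi-synchronous individual responses to the shared stimulus. This package
quantifies that synchrony, attributes it to individual audience members, and
links it to psychological covariates.

## The dyadic statistic

The core statistic is surrogate synchrony (SUSY) for a pair of feature
series on a common uniform grid:

1. **Segmentation.** Both series are cut into consecutive non-overlapping
   segments of 30 s; a trailing partial segment is dropped.
2. **Lagged cross-correlations.** Within each segment, Pearson correlations
   of `x[t]` with `y[t + tau]` are computed for integer-sample lags up to
   +/- 5 s — an 11-lag window at 1 Hz spanning the ten-second
   cross-correlation range `L`. Correlations use the truncated overlap of
   the two segments (length `segment - |tau|`); lags whose overlap or
   non-missing support falls below `min_overlap_fraction` (default 0.8) of
   the segment, or where either side is constant, are undefined and
   excluded from means rather than zero-filled.
3. **Fisher Z aggregation.** Correlations are transformed by
   `arctanh` after clipping to +/- 0.999 (so identical segments with
   `r = 1` stay finite), averaged over defined lags within a segment, then
   over segments. The non-absolute mean is kept: `Z > 0` is in-phase,
   `Z < 0` anti-phase synchrony. Positive lag means the second series lags
   the first; because the window is symmetric the aggregate is
   direction-free.
4. **Surrogate null.** Surrogates realign the segment *sequence*: each
   surrogate pairs segment `i` of `x` with segment `sigma(i)` of `y`, where
   `sigma` is a random derangement (no segment is paired with itself), and
   re-applies the same aggregation. The default draws 100 seeded
   derangements; when the number of distinct derangements is smaller
   (subfactorial of the segment count, e.g. 1 for two segments, 2 for
   three), all of them are enumerated instead. A `segment_pairs` mode uses
   each of the `n(n-1)` ordered mismatched segment pairs as one surrogate
   value, for users who prefer that reading of the surrogate space.
5. **Effect size.** `ES = (Z - mean(Zsurr)) / sd(Zsurr)` — the observed
   synchrony in surrogate standard deviations.

The implementation computes the full segment-by-segment correlation tensor
per dyad with one standardized cross-product per lag, so the observed
statistic and all surrogates share one pass over the data; a brute-force
loop implementation is kept in the test suite as an independent oracle and
agrees to `1e-12`.

### Numerical choices and degenerate inputs

* Correlation clipping at +/- 0.999 bounds a single segment's contribution
  to `|z| <= 3.8`.
* Zero-variance segments (flat signals) yield undefined correlations at
  every lag and drop out; a dyad with no usable segment is an error.
* Segments missing more than 20% of samples are unusable; within usable
  segments missing samples are excluded pairwise, with the same 80% support
  floor per lag.
* The surrogate RNG stream is keyed by the *unordered* pair identity (and
  concert, channel, scope), so `dyad_synchrony(x, y)` and
  `dyad_synchrony(y, x)` are identical, results do not depend on
  evaluation order, and reruns with one master seed are bit-stable.
* With two usable segments only one derangement exists; the effect size is
  then undefined (`sd(Zsurr)` needs at least two values) and reported
  missing with a warning.

## From dyads to audiences

An audience of `N` participants defines `N(N-1)/2` dyads per channel.
*Audience synchrony* is the mean dyadic `Z`; a participant's *synchrony
contribution* is the mean of the `N-1` dyadic `Z` values they enter. The
mean of all contributions equals audience synchrony exactly (each dyad is
counted twice and renormalized), which the tests assert to `1e-12`.

The participant-level surrogate distribution averages, for each surrogate
index `s`, the `s`-th surrogate `Z` over the participant's dyads. This
preserves between-surrogate variance, which a mean-of-means over dyad
summaries would destroy, and yields the contribution-level effect size.
The *presence test* for a channel and scope is a paired t-test of observed
versus surrogate contributions across participants.

The *composite* ("all synchronies") contribution is the mean of
within-concert, within-channel z-standardized contribution effect sizes
over HR, HRV, SCR and RR — RESP is always excluded because breathing
behaviour shows no audience synchrony. The construction of a composite is
genuinely open; z-scoring within concert and channel before averaging was
chosen so that no channel dominates through scale and concert-level offsets
cancel.

Piece-level analyses slice each recording at the piece boundaries and rerun
the full pipeline (segmentation, surrogates, contributions) per piece;
pieces shorter than two segments are skipped with a warning.

## Mixed-model inference

Associations between synchrony contributions and psychological covariates
are estimated with random-intercept linear mixed models (lme4, REML):

```
ES_contribution ~ covariates + (1 | concert)
```

* **Centering.** Affect-change, experience-factor and piece-item predictors
  are centered within concert, isolating within-concert variance.
  Personality traits are left uncentered, as traits plausibly carry no
  between-concert structure worth removing. Group-constant predictors
  under centering become all-zero and are rejected as degenerate rather
  than silently estimated.
* **Degrees of freedom.** t-statistics use residual degrees of freedom
  `n - p`. With several hundred observations the difference from
  finite-sample corrections is negligible; the rule is stated so results
  are exactly reproducible.
* **Variance accounting.** The random-effect share is
  `100 * var(intercept) / (var(intercept) + var(residual))`; model r² is
  the squared correlation of fitted and observed values, in percent.
* **Singular fits** (zero intercept variance) are kept with a warning;
  with a single group the model reduces to ordinary least squares, which
  the tests check against `lm` to `1e-6`.
* **Affect change** enters as `(pre - post) / SD(pre)` per scale, so a
  positive value is a decline; the group-level version of the same formula
  is the reported effect size. The convention is antisymmetric under
  swapping pre and post only up to the SD reference, which changes with
  the swap.
* **Piece contrasts** use a categorical piece predictor with a concert
  random intercept and all pairwise contrasts (emmeans) under Holm
  correction — raw p-values are reported within substantive models,
  matching common practice for these hierarchical analyses, while the
  post-hoc piece comparisons are corrected. A rank string such as
  `"Dean > Brahms > Beethoven"` is emitted when contrasts separate the
  pieces.
* An optional two-pass mode refits a model keeping only first-pass
  significant predictors, a multicollinearity guard for the nine
  correlated piece-experience items.

## The synthetic-data generator

No public audience-physiology dataset accompanies this problem, so the
package ships a simulator whose defaults define the study conditions used
throughout the tests:

* **Shared driver.** Per concert, a latent arousal proxy: AR(1)
  (coefficient 0.9) smoothed by a 5-s moving average and standardized — a
  smooth, band-limited stand-in for the stimulus. The smoothing window is
  configurable; disabling it recovers a pure AR(1), whose lag-1
  autocorrelation the tests verify against theory.
* **Coupled channels.** Participant `i`'s HR/HRV/SCR/RR series is
  `kappa[i] * driver(t - lag[i]) + AR(1) noise` (noise coefficient 0.6, SD
  1.0 relative to the unit-variance driver), standardized and mapped
  affinely into plausible channel units (e.g. 70 +/- 6 bpm) — affine maps
  leave every correlation unchanged. Coupling is
  `0.5 + sum(effect_k * z(covariate_k)) + N(0, 0.15)`, truncated at zero
  (an `allow_negative_coupling` switch permits planted anti-phase).
  Response lags are drawn once per participant, uniform in +/- 2.5 s:
  lags constant over a concert are the simplest dynamics consistent with
  inter-individual response latencies, and +/- 2.5 s keeps every dyadic
  lag difference inside the +/- 5-s correlation window.
* **Uncoupled RESP.** Breathing behaviour is an independent per-participant
  oscillator (base frequency uniform in 0.2-0.3 Hz with slow AR(1)
  frequency drift), so its ground-truth coupling is exactly zero and the
  pipeline should find no RESP synchrony.
* **Planted covariate structure.** Default effects on coupling: Openness
  +0.15, Extraversion -0.10, Neuroticism -0.10 per covariate SD; the two
  remaining traits are null. PANAVA affect is generated pre/post with
  planted group effect sizes (negative-activation decline 0.37,
  positive-activation 0.08, valence -0.10). Experience factors F1-F7 are
  independent standard normals (generated at the factor-score level;
  item-level factor analysis is out of scope), and nine 1-5 piece items
  get piece-specific means. Effect magnitudes are not dictated by any
  reference; they were fixed once at values a field study of ~600
  participants could plausibly detect.
* **Scale.** Defaults are 11 concerts of 60 participants, 900-s recordings
  (three 300-s pieces) at a 1-Hz feature rate — 30-sample segments and
  +/- 5-sample lags. Full concerts are an order of magnitude longer; 900 s
  keeps a full 11-concert simulation plus all-pairs synchrony in the
  minutes range while preserving 30 segments per recording. Per-piece
  coupling multipliers exist but default to 1.
* **Raw signals.** For end-to-end exercise of the feature stage, the
  generator can emit inter-beat intervals (beats stepped so `60/IBI`
  tracks target HR), a respiration waveform (sinusoid with instantaneous
  frequency `RR/60`), and an electrodermal trace (slow tonic drift plus
  Poisson impulses, rate modulated by the driver, convolved with a
  bi-exponential kernel).

What the simulator does *not* emulate: real music audio and its temporal
structure, movement and measurement artifacts, item-level questionnaire
responses, device-specific raw formats, or nonstationary coupling within a
piece. Passing tests therefore demonstrate that the pipeline measures what
it claims under a known, stationary coupling model — not that real concert
audiences behave like the simulator.

## Feature derivation

The raw-to-feature operators are deliberately simple, documented versions
of the standard steps:

* **HR**: `60 / IBI` at beat times, linearly interpolated to the grid.
* **HRV**: RMSSD (root mean square of successive IBI differences, in ms)
  in 30-s sliding windows centered on grid points — the window matches the
  SUSY segment length, so segment-level HRV variation is what the
  synchrony stage sees. One successive difference (two beats) suffices for
  a defined value; emptier windows are missing.
* **RR/RESP**: peak detection on the belt waveform (local maxima, minimum
  prominence 0.25 x SD, minimum spacing 1.5 s); RR is `60 /` inter-peak
  interval interpolated to the grid, RESP is the z-scored waveform
  resampled with phase preserved.
* **SCR**: the trace minus a centered 20-s moving-median tonic estimate,
  negative residuals clipped at zero. Moving-median detrending replaces
  model-based deconvolution of electrodermal activity: only the phasic
  component's temporal shape matters for cross-correlation, and the median
  is robust to the impulses themselves.

Missing feature samples propagate as explicit `NA` and are excluded
pairwise downstream.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, among smaller cases: a
50-participant audience (1225 dyads) for combinatorics; 200 independent
AR(1) dyads of 20 segments for null calibration (the surrogate null is
approximately, not exactly, standard normal, so the two-sided rejection
rate at `|ES| > 1.96` is only required to lie in a band around 5%);
coupling sweeps over kappa in {0, 0.25, 0.5, 1}; ten 30-participant
single-concert simulations for the presence/RESP-null pattern; and one
full 11 x 60 simulation for personality-sign recovery. These sizes were
chosen as the smallest at which the respective effects are
unambiguous.

## Known limitations

* The surrogate count ambiguity (random derangements versus the full
  `n(n-1)` mismatched-pair space) is exposed as `surrogate_mode`; the two
  modes give the same `Zsurr` mean in expectation but different
  granularity of the null.
* Equal weighting of lags (rather than weighting by overlap length) is a
  convention; at the default geometry overlaps differ by at most 17%.
* Contribution effect sizes of the same audience share dyads and are not
  independent across participants; the presence t-test treats them as
  exchangeable, which matches the reference analysis but is
  anti-conservative for very small audiences.
* Piece-level surrogate pools are small (10 segments per 300-s piece),
  making piece-level ES noisier than concert-level ES.
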