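---
title: "Linking subcortical volume asymmetry to lateralized alpha modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking subcortical volume asymmetry to lateralized alpha modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hemilat)
library(dplyr)
```

## The scientific question

During covert visuospatial attention, posterior alpha-band (8–13 Hz) power
decreases over the hemisphere contralateral to the attended hemifield and
increases ipsilaterally. Individuals differ reliably in how *balanced* this
modulation is between their two hemispheres, and one candidate source of
that variability is structural: hemispheric asymmetries in the volume of
subcortical structures (thalamus and basal ganglia) that participate in
cortico-subcortical attention circuits.

`hemilat` implements the full analysis chain for testing that idea on
sensor-level MEG-style data plus per-hemisphere volumetric tables:

1. time–frequency power with a fixed-cycle sliding Hanning window,
   planar-gradiometer pair combination;
2. per-sensor **modulation index**
   $\mathrm{MI}_k = (P_k^{\text{att-R}} - P_k^{\text{att-L}})
   / (P_k^{\text{att-R}} + P_k^{\text{att-L}})$
   from trial-averaged alpha power in a pre-target window;
3. group-level selection of mirror-symmetric **ROI** sensor pairs with the
   largest right-minus-left MI difference;
4. the **hemispheric lateralization modulation**
   $\mathrm{HLM} = \overline{\mathrm{MI}}_{\text{right ROI}} +
   \overline{\mathrm{MI}}_{\text{left ROI}}$, overall and per task
   condition;
5. the **lateralization volume**
   $\mathrm{LV}_s = (V_s^{\text{right}} - V_s^{\text{left}})
   / (V_s^{\text{right}} + V_s^{\text{left}})$ for seven bilateral
   subcortical structures;
6. exhaustive AIC/BIC subset selection over the seven LV regressors for a
   linear model of HLM, with VIF, one-sample and Shapiro–Wilk checks;
7. multivariate multiple regression of the four condition-wise HLM values
   on the selected LVs, with Hotelling per-regressor and Wilks nested
   tests;
8. behavioral asymmetry
   $\mathrm{BA} = (x^{\text{att-R}} - x^{\text{att-L}})
   / (x^{\text{att-R}} + x^{\text{att-L}})$ for accuracy and RT, refit
   with the winning structural model.

Because raw recordings for such studies are rarely shareable, the package
treats a **synthetic-cohort generator** as a first-class module: it draws
volume tables and sensor-level epochs whose ground-truth coupling between
LV and HLM is known exactly, so every downstream stage can be tested for
parameter recovery, calibration and determinism.

## The generative model

For subject $i$ with LV vector $\ell_i \in (-1,1)^7$:

$$\mathrm{HLM}_i = \beta_0 + \sum_s \beta_s \,\ell_{is} + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2).$$

Condition-wise targets are, by default, the overall target plus
independent $\mathcal N(0, \sigma_c^2)$ perturbations; a second mode gives
each condition its own coefficient vector (used to emulate
condition-specific structure–function coupling, e.g. thalamus driving the
easiest condition and caudate the hardest).

Sensor-level epochs realize those targets physically. Each mirror pair of
locations carries two planar channels. On a trial with condition target
$h$ the per-sensor target MI is $\pm m + h/2$ (sign by hemisphere, $m$ the
common modulation depth), scaled by 0.25 on non-hotspot pairs; the alpha
amplitude on attend-right vs attend-left trials is set to
$A\sqrt{1 \pm \mathrm{MI}}$ so the implied attend-right/attend-left power
ratio is $(1+\mathrm{MI})/(1-\mathrm{MI})$ and the two hemispheric ROI
means sum to $h$ in expectation. Broadband $1/f$ noise is added per
channel.

### Defaults and what they emulate

| Parameter | Default | Why |
|---|---|---|
| `n_subjects` | 33 | the cohort size of the study design being modeled |
| `n_trials_per_condition` | 128 | 2 × 256 trials over four load/salience conditions |
| `epoch_window` | −1.5…0.5 s | covers the −850–0 ms analysis window with margin for the longest alpha-band taper; a shorter window than the recorded −3…1 s epochs, purely for economy, and configurable |
| `sampling_rate` | 250 Hz | alpha analysis is unaffected far above Nyquist; configurable up to the recorded 1000 Hz |
| `n_sensor_pairs`, `n_roi_true` | 10, 5 | a selectable ROI needs spatial contrast; 5 hotspot pairs mirror the 5-pair ROI |
| `modulation_depth` | 0.1 | typical magnitude of attentional alpha MI at posterior sensors |
| `coupling_betas` | (Th −2.19, CN 0.92, GP 0.51) | the winning-model coefficient estimates, reused as generator ground truth |
| `hlm_noise_sd` | 0.050 | calibrated by simulation so the mean *fitted* adjusted R² of the three-regressor model on cohorts of 33 is ≈ 0.38; note that at n = 33 the fitted adjusted R² is upward-biased relative to its population value (≈ 0.43 observed when the population value is 0.38), so the calibration is done on the fitted quantity, which is what any single-cohort report shows |
| `condition_sd` | 0.02 | free parameter: no per-condition effect sizes are available to copy, so condition targets scatter mildly around the overall target |
| LV distributions | Th (−0.0123, 0.0121), CN (0.0115, 0.0285), Put (−0.0149, 0.0285), Acc (−0.1141, 0.0746) | the reported group means ± sd; GP, Hipp and Amyg showed no robust asymmetry and default to mean 0 with comparable spread (sd 0.02–0.03) |

The generator does **not** simulate delay-length jitter (epochs are
target-locked and stationary — only the pre-target window is analysed),
eye movements, frequency-tagging signals, realistic 306-channel geometry,
or volume-conduction mixing between sensors. Consequently, passing tests
demonstrate that the *analysis* recovers what the generative model puts
in; they cannot certify performance against physiological confounds that
the generator omits.

## Spectral estimation choices

* **Fixed-cycle windows.** At frequency $f$ the window is
  $3/f$ seconds (300 ms at 10 Hz), demeaned, Hanning-tapered, zero-padded
  to the next power of two; power is read at the single padded-FFT bin
  nearest $f$ (no neighbor averaging), at 10 ms center-time steps snapped
  to the nearest sample.
* **Normalization.** The windowed spectrum is scaled by
  $2/\sum w$ (taper mass), putting power on an amplitude-squared scale
  that is comparable across window lengths. Without this, longer
  low-frequency windows would dominate raw magnitudes; with it, a
  noiseless 10 Hz sinusoid peaks at the 10 Hz grid point. The MI is a
  ratio of powers at one sensor and frequency band, so this scale choice
  cancels there.
* **Edges.** A frequency's value is missing (`NA`) at center times where
  its full window does not fit; band/window averages exclude missing
  cells. With the default epoch and band this never affects the
  −850–0 ms alpha analysis.
* **Per-window demeaning** stands in for the 1 Hz high-pass of a real
  preprocessing chain; the MI is self-normalizing, so no baseline
  correction is applied anywhere.
* **Averaging order.** Power is averaged over trials, band frequencies
  and window times per cue side first; the MI is then formed from the two
  per-sensor scalars. Planar pairs are combined by summing power before
  any averaging.

## Index and model conventions

* The ROI is selected **once**, from the unweighted group-mean MI map
  over all trials, and reused for condition-wise HLM (the study fixed its
  sensors of interest before the condition analyses; a per-condition
  re-selection would let sensor identity vary with condition and is
  deliberately not the default). Ties in the pair ranking break by
  ascending pair label, for determinism.
* HLM lies in $(-2, 2)$: it is the sum of two means of quantities in
  $(-1, 1)$. Negative HLM means stronger left-hemisphere modulation.
* The exhaustive search fits all $2^7 - 1 = 127$ intercept-plus-subset
  models by ordinary least squares. A mixed-effects formulation is
  unidentifiable with one observation per subject, so fixed-effects OLS
  is the only identifiable reading; "subject intercepts only" in the
  nested comparisons is correspondingly a single shared intercept.
* AIC is $-2\log L + 2(k+2)$, counting the intercept and the residual
  variance, exactly as `stats::AIC()`; all constants retained so values
  are comparable across subsets. No multiple-testing correction is
  applied across the 127 candidate models — the search reports raw
  criteria.
* The condition-wise model treats the four HLM values as four outcome
  columns of one multivariate regression (per-condition coefficients
  could not exist for a summed outcome). Per-outcome inference is
  identical to four univariate fits; the multivariate content is in the
  residual covariance.
* The per-regressor across-outcome test is Hotelling's $T^2$ on one
  coefficient row, $F = \frac{v_e - p + 1}{v_e\,p} T^2$ on
  $(p,\ v_e - p + 1)$ df — $(4, 26)$ at $n = 33$, $k = 3$. Nested model
  comparisons use Wilks' $\Lambda$ with Rao's F approximation, matching
  `anova.mlm`; the original report's printed df conventions for these
  comparisons are ambiguous, so the package documents its own (standard)
  ones rather than guessing.
* One-sample lateralization tests are two-sided t tests; normality is
  Shapiro–Wilk via `stats::shapiro.test`. RT asymmetries average correct
  trials only by default (`rt_correct_only`), a documented switch since
  the original choice is unstated.

## Numerical and degenerate-input behavior

Nonpositive powers, voxel counts or behavioral metrics are errors naming
the offending sensor/row; missing hemisphere partners (sensors or volume
rows) are errors; rank-deficient designs, zero-variance regressors,
exactly collinear VIF inputs, and too-few-observation fits are errors
rather than silent `NA`s. All generators are pure functions of
`(config, seed)`; the pipeline report is byte-reproducible and its JSON
serialization carries a config hash instead of a timestamp.

## Problem sizes used by the tests and the acceptance script

Simulation-heavy checks run on the statistical layer (volumes + coupling
targets, no epoch synthesis): test-size calibration uses 2000 null
cohorts of 33; coefficient recovery 500 (script: 300) cohorts of 33;
subset-search recovery 100 cohorts of 200. Epoch-level checks use small
arrays (3–12 subjects, 3–6 mirror pairs, 8–48 trials per condition); the
acceptance script's end-to-end cohort uses 33 subjects with 8 pairs and
32 trials per condition. These sizes are the package's choice of
desk-scale defaults for its own verification; all are configurable.

## Known limitations

* AIC-based exhaustive search is not selection-consistent: with four
  irrelevant candidates its probability of returning *exactly* the true
  subset plateaus near $0.843^4 \approx 0.5$ regardless of effect
  strength, because each irrelevant regressor enters with probability
  $P(\chi^2_1 > 2) \approx 0.157$. BIC, reported alongside, is
  consistent and recovers the exact subset in >90% of strong-effect
  cohorts at $n = 200$.
* Realized sensor MI is attenuated toward zero by additive broadband
  noise (noise power enters both the numerator's terms); recovery of HLM
  targets is exact only in the noise-free limit. The structural coupling
  analyses are therefore best simulated on the statistical layer, where
  targets are exact.
* The generator's spatial profile (hotspot vs non-hotspot pairs) is a
  caricature of real topographies; ROI selection tests exercise the
  selection logic, not realistic sensor geometry.
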