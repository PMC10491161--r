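---
title: "Methods: quantifying Drosophila behavior and clock-neuron activity around dusk"
author: "dusktools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Drosophila behavior and clock-neuron activity around dusk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dusktools)
```

## Scope and scientific setting

Flies under a 12:12 light:dark cycle are crepuscular: a burst of activity
at lights-on, a midday siesta, a slow anticipatory rise of locomotion
before lights-off, and a rapid transition from the evening activity peak
into consolidated night sleep shortly after dusk. `dusktools` quantifies
this program from Drosophila Activity Monitor (DAM) beam-break counts —
sleep under the 5-minute inactivity rule, post-dusk sleep-onset latency,
windowed sleep amounts and their changes across manipulation days,
evening anticipation slope, and evening peak phase — and, on the
physiology side, extracts spike trains and firing rates from fluorescence
voltage-indicator recordings of clock neurons. A statistics layer mirrors
the conventions of the field: each experimental genotype is compared
against both of its genetic controls with an omnibus test, planned
post-hoc comparisons, and a normality gate.

Because no raw recordings ship with the package, a synthetic-data module
generates DAM files and voltage traces with exact ground truth; every
analysis stage is validated against it and against independent
brute-force oracles in the test suite.

## Behavioral metrics

**Zeitgeber alignment.** ZT is clock time minus lights-on, modulo 24 h.
Only whole ZT days are analysed; partial leading/trailing data are
dropped and reported. Under constant darkness, circadian time continues
the entrained phase, so the same projected lights-on defines CT0.
Daylight-saving transitions are out of scope: timestamps are treated as
local, monotone, and 1-min resolved. Monitor rows whose status code is
not 1 are retained verbatim but flagged; flagged minutes are excluded
from every downstream metric and break inactivity runs, a conservative
choice that never fabricates sleep from missing data.

**Sleep scoring.** A minute is asleep iff it belongs to a maximal run of
zero-count minutes at least `threshold_min` long (default 5). Scoring is
idempotent, total sleep equals the summed bout durations, and raising the
threshold can only remove sleep. Bouts crossing a day boundary are split
with the linkage recorded, so per-day bookkeeping stays additive.

**Sleep-onset latency after dusk.** The day segment from dusk onward is
re-scored and the onset is the first minute of the first qualifying run.
A bout already in progress at dusk therefore yields onset exactly at dusk
— the latency is floored at zero, matching the floor that dusk imposes on
the measurement. The alternative of discarding straddling days is exposed
via `straddle = "exclude"`. Flies with no post-dusk sleep are reported as
missing, not zero, and counted in the attrition table. Because the floor
skews the distribution, onset is always routed down the nonparametric
branch of the statistics layer, whatever the normality gate would say.

**Windows.** All windows are half-open `[start, end)` in ZT hours, so
morning ZT0–6 and afternoon ZT6–12 partition the light phase exactly.
Sleep change is manipulation-day minus baseline-day minutes in a window;
negative values are sleep loss.

**Dead-fly filter.** Flies with zero counts across the final 12 h of the
protocol are excluded from all metrics (configurable trailing window).

## Evening anticipation and phase

The anticipation slope is the per-day OLS slope of binned activity
(counts/min per bin, default 30-min bins) against bin-start ZT over the
three hours before the transition, averaged across analysis days. Three
hours isolates the anticipatory ramp from the siesta trough; the window
is configurable (a 6-h variant is one argument away). The half-open
window ends strictly before the transition, so the lights-off startle
artifact never enters the fit.

The evening peak phase smooths the binned daily profile with a centered
circular moving average and reports the bin-start ZT of the maximum
inside a ZT6–14 search window (ties to the earliest bin; constant
profiles are flagged undefined). The window spans both sides of dusk so
phase advances produced by short-period clocks remain visible. The
smoothing width is the nearest odd bin count covering `smooth_hr` (2 h at
30-min bins uses 5 bins). This estimator is a deliberate re-specification
of external phase tools, not a reproduction of their internals: absolute
phase values carry an estimator-specific offset (the post-dusk activity
collapse pulls the smoothed argmax earlier), but differences between
groups measured with the same estimator recover injected shifts to within
one bin, which is the quantity the group comparisons use.

## Voltage-imaging spike pipeline

Recordings are fluorescence samples at 849 Hz; spikes of the indicator
are fast negative-going deflections riding on slow (1–8 Hz) subthreshold
oscillations over a photobleaching decay. The pipeline is:

1. **ROI selection**: pixels are k-means clustered (k = 2 by default, the
   minimal signal/background split) on standardized temporal profiles;
   the signal cluster is the one whose mean trace retains the most
   variance after polynomial detrending. Clustering is seeded and the
   caller's RNG stream is left untouched.
2. **Photobleach detrending**: a least-squares polynomial over the whole
   trace is subtracted; degree 3 by default (the published procedure
   names only "a polynomial curve"), configurable.
3. **Low-pass filtering**: second-order Butterworth with normalized
   cutoff 0.5. The cutoff is read as a fraction of Nyquist (~212 Hz at
   849 Hz), the convention of the major numerical environments; the
   parameter is explicit in every call. All filters are applied
   forward-backward so spike timing is phase-unbiased; the amplitude
   ratio at the cutoff is therefore 0.5 (the two passes square the -3 dB
   response). Ends are padded by odd reflection so filter transients fall
   on discarded samples.
4. **Moving baseline**: a zero-phase 1–8 Hz band-pass (order 2 per edge)
   tracks the subthreshold oscillation; its DC gain is ~0.
5. **Spike calling**: candidates are strict local minima of
   (filtered − baseline) that lie below `baseline − n_sd × σ`
   (n_sd = 2). Candidates closer than 5 ms keep only the deepest, and the
   first/last 250 ms are excluded to avoid residual edge effects.
6. **Rate**: spike count divided by recording length.

**The σ convention.** The published rule — local minima "below two
standard deviations from the estimated baseline fluorescence" — admits
two readings. Taking σ as the SD of the residual (filtered − baseline)
places the 2σ line at roughly twice the filtered sensor-noise SD; for
white sensor noise on a 60-s, 849-Hz trace, thousands of noise minima
cross such a line and precision collapses (~0.1 in our simulations), and
no realistic setting of the trace generator rescues it. Taking σ as the
SD of the estimated baseline itself calibrates the threshold to the
amplitude of the subthreshold oscillation, which sits well above the
noise floor while remaining well below spike depth; with it the pipeline
reaches precision and recall ≈ 0.99 on synthetic traces with spikes at
six noise-SDs. The package defaults to the baseline-SD reading and keeps
`sigma = "residual"` and a running-window variant as options, so both
interpretations can be audited. Manual spike curation, part of the
original workflow, is deliberately out of scope.

Two-condition rate comparisons (e.g. dawn vs dusk recordings) use the
two-tailed pooled-variance Student's t test. A calibration property is
enforced in the tests: with equal true rates at n = 7 per group the
rejection rate stays at the nominal 5%.

## Statistics layer

Planned comparisons are each experimental group against each of its
genetic controls — never all pairs. The omnibus is one-way ANOVA for
normally distributed metrics and Kruskal-Wallis (tie-corrected)
otherwise; the gate is per-group Shapiro-Wilk at α = 0.05, with any
rejection, any group smaller than three, or any zero-variance group
routing to the nonparametric branch, and every gate outcome recorded in
a decision trail. Post-hocs are the classic Bonferroni multiple
comparison t (pooled ANOVA residual mean square and its df; Welch
per-pair variant available) or Dunn's rank z with tie-corrected pooled
rank variance; p-values are multiplied by the number of planned
comparisons and capped at one. A phenotype is called only when the
adjusted p is below α against *both* controls with agreeing effect
direction.

## The synthetic generator

Wake and sleep alternate as a two-state semi-Markov process — the
simplest structure under which every metric above has exact ground truth
— and wake minutes emit Poisson counts from a crepuscular rate template.
It is an emulation of the published phenomenology, not a mechanistic
clock model. Defaults, chosen once as field-realistic values:

* baseline wake rate 1.0 counts/min; Gaussian morning peak (amplitude
  2.5, width 0.75 h) at ZT0; lights-on/off startle pulses of 8 counts
  (LD days only);
* evening anticipatory ramp of 0.8 counts/min per hour over ZT9–12;
* siesta bouts over ZT4–8 (mean 25 min, mean gap 15 min);
* post-dusk onset latency gamma-distributed with mean 20 min and SD
  10 min; consolidated night bouts (mean 45 min, mean gap 8 min);
* every generated sleep bout is at least 5 min, so generator truth and
  the scoring rule can coincide exactly.

Because a wake minute can draw a Poisson zero, raw emission could create
zero runs the scorer cannot distinguish from sleep. With
`enforce_scoring = TRUE` (default) wake zeros adjacent to a true bout are
bumped to one count and remaining wake zero-runs of threshold length are
broken every fifth minute; the perturbation is a few counts per day and
leaves slope/phase calibration untouched, while making truth-vs-scoring
agreement exact. Disabling the flag exposes the scorer to sub-threshold
quiescence for robustness testing.

Phenotype injections mirror the studied manipulations: an added onset
latency (silencing-like, applied on every day since the silencer is
maintained throughout), probabilistic suppression of afternoon siesta
bouts on the hot day only (activation-like), and an evening phase
advance. The phase advance shifts the whole evening program — ramp,
peak, and evening sleep onset — so the advanced cohort's profile is the
control profile time-shifted around dusk; a ramp-only shift would bias
the smoothed-argmax phase difference because the post-dusk activity
collapse would differ in shape between groups. Activation in constant
darkness injects no effect, reflecting the light-dependence of the
behavioral output it emulates.

Voltage traces are an exponential bleach plus a 2-Hz sinusoidal
subthreshold oscillation (amplitude 4.5 a.u., about 2.25× the 2 a.u.
sensor-noise SD), minus causal exponential spike transients (decay 5 ms,
within the physiological range of fast voltage-indicator responses) at
refractory-Poisson times, plus white Gaussian noise. Pixel movies share
one trace across signal pixels and add independent pixel noise, so ROI
recovery can be scored against the planted mask. What the generator does
*not* emulate — correlated motion artifacts, photon shot-noise scaling
with intensity, multi-neuron crosstalk, temperature physiology of the
effectors, free-running period drift in extended DD — bounds what passing
tests show about real recordings: they certify the estimators against
their stated models, not against every artifact of a rig.

## Numerical and design choices

* Bin timestamps are bin-start ZT everywhere, and the peak phase is
  reported on the same convention.
* Degenerate inputs are first-class: empty monitors, constant profiles
  (undefined phase, flagged), zero-variance groups (p = 1, no division
  by zero), all-tied ranks, constant residuals (no spikes, flagged).
* Ties in the smoothed profile resolve to the earliest bin;
  deterministic greedy deepest-first resolution in the refractory merge.
* All simulation entry points take an explicit seed, save and restore
  the caller's RNG state, and are byte-reproducible; the analysis path
  itself uses no randomness apart from the seeded k-means in ROI
  selection.
* Problem sizes used by the validation suite — cohorts of 32 flies per
  genotype over two protocol days, 60-s voltage traces, 500-replicate
  calibration loops — match the study design scales while keeping the
  whole suite around two minutes on one core.

## Worked example

```{r example, eval = FALSE}
exp <- build_experiment("E1_silencing", n_per_group = 32, seed = 42)
res <- run_experiment(exp)
print(res)
#> <dusk_analysis> E1_silencing, metric: onset
#> Kruskal-Wallis: statistic = 64.05, df = 2, P = 1.23e-14
#>   GAL4>UAS vs GAL4/+: P = 5.4e-13 [***]
#>   GAL4>UAS vs UAS/+: P = 1.85e-10 [***]
#>   trail: forced nonparametric; branch: Kruskal-Wallis + Dunn; ...
#>   verdict GAL4>UAS: significant vs both controls
```

The recovered median onset delay in this run is 45 min — the injected
value — and the verdict is significant against both controls.

## Known limitations

* The anticipation-slope window and the phase estimator's smoothing
  kernel are principled defaults, not reconstructions of any specific
  external tool; absolute values are comparable only within-package.
* The DAM reader supports the classic single-beam DAM2 42-column layout
  only.
* Sleep-architecture analyses beyond the metrics above (bout-length
  distribution fits, transition-probability metrics) are out of scope.
* The spike pipeline assumes motion-corrected input and performs no
  manual curation.
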