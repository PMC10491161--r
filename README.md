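# dusktools

Quantitative analysis of *Drosophila* behavior and clock-neuron activity
around dusk.

Flies are crepuscular: activity peaks at dawn and dusk, a siesta fills
midday, locomotion ramps up in anticipation of lights-off, and shortly
after dusk the animals drop from peak activity into consolidated night
sleep. Dissecting which evening clock neurons drive which piece of this
program requires a reproducible quantitative toolchain, and that is what
this package provides — for chronobiologists working with Drosophila
Activity Monitor (DAM) beam-break data and for physiologists analysing
fluorescence voltage-imaging traces of clock neurons.

## What it computes

**Behavior, from DAM monitor files (classic DAM2 42-column layout):**

* sleep scoring by the 5-minute inactivity rule: minute *m* is asleep iff
  it lies in a maximal run of zero-count minutes of length ≥ 5;
* sleep bouts, windowed sleep amounts over half-open ZT windows
  (ZT0–6, ZT6–12, ZT12–24), and baseline-vs-manipulation sleep change;
* post-dusk sleep-onset latency: the start of the first qualifying
  inactivity run at or after dusk (a bout straddling dusk gives onset
  exactly ZT12);
* evening anticipation slope: OLS slope of 30-min-binned activity
  (counts/min) against bin-start ZT over ZT9–12, averaged across days;
* evening peak phase: argmax of the smoothed binned profile in ZT6–14.

**Physiology, from voltage-indicator traces (849 Hz by default):**
k-means ROI selection on pixel time courses → polynomial photobleach
detrending → zero-phase second-order Butterworth low-pass (0.5 of
Nyquist) → 1–8 Hz band-pass moving baseline → negative-going spike
calling at local minima below `baseline − 2σ` → firing rate =
count / duration, with a pooled two-tailed t test for two-condition
comparisons.

**Statistics:** one-way ANOVA + Bonferroni planned comparisons or
Kruskal-Wallis + Dunn's post hoc, gated by per-group Shapiro-Wilk
(sleep onset is always treated as non-normal), with each experimental
genotype called significant only against *both* of its genetic controls.

**Synthetic data:** a seeded generator emits DAM-format monitors and
voltage traces with exact ground truth (two-state semi-Markov sleep,
Poisson wake counts, refractory-Poisson spikes), plus five ready-made
three-genotype experiment scenarios (silencing-like onset delay,
activation-like afternoon sleep loss in LD, its no-effect DD
counterpart, an evening phase advance, and a null).

## Worked example

```r
library(dusktools)

exp <- build_experiment("E1_silencing", n_per_group = 32, seed = 42)
res <- run_experiment(exp)
print(res)
#> <dusk_analysis> E1_silencing, metric: onset
#> Kruskal-Wallis: statistic = 64.05, df = 2, P = 1.23e-14
#>   GAL4>UAS vs GAL4/+: P = 5.4e-13 [***]
#>   GAL4>UAS vs UAS/+: P = 1.85e-10 [***]
#>   trail: forced nonparametric; branch: Kruskal-Wallis + Dunn; 2 planned Dunn comparison(s), tie-corrected
#>   verdict GAL4>UAS: significant vs both controls

med <- tapply(res$metrics$onset, res$metrics$role, median, na.rm = TRUE)
60 * (med[["experimental"]] - med[["control"]])
#> [1] 45
```

The scenario injects a 45-minute sleep-onset delay into the experimental
genotype only; the pipeline recovers a 45-minute median delay, the
Kruskal-Wallis omnibus across the three genotypes is decisive, and the
Dunn comparisons are significant against both controls, so the verdict
is a real phenotype call.

For raw files on disk, `read_dam_monitor()`, `light_schedule()` and
`to_fly_series()` get you from a DAM text file to ZT-aligned per-fly
series; `write_experiment()`/`read_experiment()` round-trip whole
experiments through DAM files plus a plain-text config, and
`inst/cli/dusk-analyze.R` is a thin command-line wrapper over the same
functions.

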