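---
title: "Quantifying in vivo calpain activity from FRET fibre photometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vivo calpain activity from FRET fibre photometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(photofret)
library(dplyr)
```

## The measurement

A genetically encoded calpain sensor is an ECFP–linker–EYFP fusion: while the
α-spectrin-derived linker is intact, exciting the ECFP donor (415 nm LED)
yields EYFP acceptor emission (500–540 nm) by FRET. Calpain cleaves the
linker, so acceptor emission under donor excitation reports the *intact*
sensor pool — more calpain activity means less FRET. A fibre coupled to a
camera records the mean pixel intensity of the fibre-face region of interest
(ROI) at roughly 41 frames per second, with excitation frames strictly
interleaved with LED-off frames that serve as a control for ambient light and
motion.

Each recording session is one minute with no LED (settling) followed by one
minute of interleaved recording. Sessions are run immediately before dosing
(hour 0) and at 1, 2 and 3 h post-administration.

## The statistics the pipeline computes

* **Session FRET** — mean ROI intensity of LED-on frames minus mean of the
  interleaved LED-off frames, over the interleaved minute
  (`compute_fret()`). Subtracting the interleaved control cancels anything
  common to both LED states.
* **ΔFRET** — percent change from the same day's pre-treatment baseline,
  `100 (F_t − F_0)/F_0` (`compute_delta_fret()`). The hour-0 value is 0 by
  construction. A calpain *inhibitor* spares the sensor, so the intact pool
  grows and ΔFRET is positive; an *activator* (an ionomycin-like calcium
  ionophore) drives it negative.
* **Day summaries** — maximum and minimum ΔFRET over the recording day and
  the trapezoidal area under the ΔFRET–time curve over 0–3 h, in %·h
  (`summarize_day()`, `auc_trapezoid()`).
* **Cohort statistics** — two-way repeated-measures ANOVA (time ×
  treatment) with a REML mixed-model fallback for missing cells, one-way
  ANOVA with Tukey HSD across doses, paired/unpaired t-tests, Pearson
  correlations, the strict `<100` EYFP⁺-neuron histology exclusion and the
  matched-data inclusion rule (`rm_two_way_anova()` and friends).

## The mechanistic simulator

Raw in vivo recordings for this kind of experiment are rarely deposited, so
the package ships a generator that produces full frame-level sessions with
the structure the analysis assumes, plus closed-form oracles to validate the
pipeline against.

The intact sensor pool obeys

$$\frac{dS}{dt} = k_{syn} - \bigl(k_{deg} + k_{cl}\,a(t)\bigr)\,S,$$

continuous synthesis balanced by basal turnover and activity-proportional
cleavage. Before dosing the pool sits at the steady state
$S_{ss} = k_{syn}/(k_{deg} + k_{cl} a_0)$, which is what makes repeated
within-animal baselines meaningful. Drug pharmacodynamics scale activity as
$a(t) = a_0\,(1 \mp m\,B(t))$ with $B(t)$ a Bateman onset/washout curve
normalised to unit peak — the minimal two-rate shape with distinct onset and
washout. The ODE is integrated with fixed-step RK4 at ≤1 s steps; against
the closed-form relaxation its error is well under 0.1%. Because the
equation is linear in $k_{syn}$, the cohort generator solves once per
treatment and rescales exactly per animal.

Under sustained fractional inhibition $f$ with $k_{deg}=0$ the
re-equilibrated pool gives the master oracle
$$\Delta\mathrm{FRET}_{ss} = 100\,\frac{f}{1-f},$$
(11.1%, 33.3% and 100% at $f$ = 0.1, 0.25, 0.5), generalised to
$100\,k_{cl}a_0 f/(k_{deg}+k_{cl}a_0(1-f))$ for $k_{deg}>0$
(`delta_fret_steady_state()`). The acceptance checks drive the *entire*
pipeline — frame rendering, parsing, control subtraction, baselining — and
compare to this closed form.

### Default conditions

Chosen once as a realistic embodiment of the recording set-up, and used by
every simulation in the package:

| parameter | default | rationale |
|---|---|---|
| `fps` | 41 /s | camera rate of the rig; 60 s interleaved ⇒ 2460 frames, ~1230 per LED state |
| `k_syn` | 60 units/h | sets $S_{ss}=100$ counts at unit gain — a comfortable camera signal |
| `k_deg` | 0.1 /h | slow activity-independent turnover |
| `k_cl` | 0.5 /h per activity-unit | cleavage dominates turnover at basal activity; pool time constant ≈ 1.7 h, consistent with responses that develop over the 3 h day |
| `a0` | 1 | basal activity defines the unit |
| `gain`, `ambient` | 1, 5 counts | arbitrary optical scale; ΔFRET is invariant to both |
| `noise_sd` | 2 counts | 2% per-frame noise; averaged over ~1230 frames per state it leaves a ΔFRET floor of ≈0.1% |
| `bleach_rate` | 2×10⁻⁶ /s of LED-on time | brief interleaved recordings are designed to make photobleaching negligible; over a day's ~120 LED-on seconds this biases ΔFRET by only ≈−0.02% |
| jitter CV | 0.2 on `k_syn`, `gain` | lognormal between-animal variation in viral expression and optical coupling |
| inhibitor `k_on`, `k_off` | 12 /h, 0.4 /h | onset apparent within minutes, washout over hours |

The ~41 fps × 60 s arithmetic gives 2460 frames per interleaved window;
whether one counts all frames or only the ~1230 excitation frames as
"measurements" is a bookkeeping choice, so the generator exposes `fps` and
the window durations rather than fixing either convention.

Treatment order across days uses a cyclic Latin square so each treatment
occupies each ordinal position equally often; a ≥24 h washout between
treatment days is carried as manifest metadata.

### What the simulator does and does not emulate

It emulates: the interleaved frame structure and no-LED lead-in, pre-dose
steady-state baselines, drug onset/washout, cumulative-exposure
photobleaching, slow common-mode motion artifacts (a ~17 s sinusoid with
random phase), additive Gaussian camera noise, and between-animal expression
variability. It does **not** emulate camera shot noise statistics,
hemodynamic or pH artifacts, movement-induced fibre-coupling changes that
differ *between* LED states, or calcium dynamics upstream of calpain — so a
passing suite validates the arithmetic and the statistical behaviour of the
pipeline, not the biological fidelity of any particular recording. Because
the per-animal jitter acts on `k_syn` and `gain`, both of which cancel in
ΔFRET, simulated between-animal ΔFRET variability is noise-dominated and
much smaller than in real animals; detection power on simulated cohorts is
correspondingly optimistic.

## Numerical and design choices

* **Analysis window.** Only the interleaved minute enters the FRET mean; the
  no-LED lead-in is settling time. The control is the interleaved LED-off
  stream within the same window, not the lead-in.
* **Interleave parity.** Sessions start LED-off, but the LED-state column is
  authoritative everywhere downstream; nothing assumes parity.
* **Missing timepoints.** Max/min ΔFRET use the hours available; the AUC
  requires the complete 0–3 h grid and is otherwise `NA` — integrating
  across a gap would silently change the quantity, so the pipeline refuses
  rather than interpolates. Cohort-level missing cells route the ANOVA to
  the mixed-effects fallback instead.
* **Failed baselines.** $F_0 \le 0$ is an error, not a warning: ΔFRET's sign
  flips for a negative denominator, which would corrupt every downstream
  summary.
* **Zero-variance t inputs** are errors rather than `t = 0`; silent
  degeneracy usually means a broken upstream table.
* **Mixed-model fallback.** A random intercept per animal with Satterthwaite
  denominator df is the minimal structure faithful to a "mixed-effects
  two-way ANOVA"; no sphericity correction is applied by default. In the
  balanced, compound-symmetric limit it reproduces the classical F ratios
  (this is tested).
* **Null calibration.** The null for the treatment test is a cohort with two
  vehicle arms. The hour-0 cells are structural zeros; the treatment test
  compares subject×treatment means, which remain exchangeable under the
  null, so the classical F stays exactly calibrated — the suite confirms a
  rejection rate near 0.05 over 500 simulated null cohorts.
* **Genotype** is carried through tables but not modelled by default; the
  statistics layer pools genotypes, with the column available for users who
  want to model it.
* **Problem sizes.** The validation suite uses 8-animal cohorts, 200
  replicates for direction/power properties and 500 for null calibration —
  large enough for stable rates at the scales of interest.

## Worked example

```{r example}
params <- sensor_params()
f <- inhibition_for_steady_state(params, target_pct = 30)
spec <- cohort_spec(
  n_animals = 8,
  treatments = list(drug_profile("vehicle"),
                    drug_profile("inhibitor", magnitude = f, dose = 2)),
  seed = 42
)
experiment <- simulate_cohort(spec, params) |> process_experiment()
glance(experiment)
experiment$summaries |> group_by(treatment) |>
  summarise(mean_max = mean(max_delta_fret), mean_auc = mean(auc))
tidy(rm_two_way_anova(experiment$delta_fret))
```

```{r plot}
autoplot(experiment)
```

## Limitations

The pipeline reproduces the published analysis method; it does not improve
on it. In particular there is no isosbestic channel in this recording
configuration, so slow artifacts that *differ* between LED states (true
wavelength-dependent motion coupling, bleaching of the reporter itself) are
not separable from signal; photobleaching correction is deliberately out of
scope. Exact replication of any specific animal study's F statistics is not
possible from summary data, and GraphPad's mixed-effects denominator-df
conventions are not documented, so mixed-model p-values may differ in the
third decimal from other software on the same data.
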