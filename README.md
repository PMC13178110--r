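# photofret

Analysis of in vivo fibre-photometry recordings of a FRET-based calpain
biosensor, plus a mechanistic simulator for validating the pipeline.

## The problem

A genetically encoded calpain sensor (ECFP–linker–EYFP) reports protease
activity by loss of FRET: while the α-spectrin-derived linker is intact,
415 nm donor excitation produces EYFP acceptor emission; calpain cleavage
abolishes it. In vivo, a fibre coupled to a camera records the mean pixel
intensity of the fibre-face region of interest at ~41 frames/s, with
excitation frames strictly interleaved with LED-off control frames. The
question the pipeline answers: does a systemically administered calpain
inhibitor (or activator) change brain calpain activity, and with what time
course, in each animal and across a cohort?

`photofret` is for preclinical researchers running such experiments: it
takes the frame-level recordings (CSV or Bonsai-style XLSX) plus an
experiment manifest, and produces per-animal ΔFRET time courses, day
summaries, and the cohort statistics.

## The method

For each session, FRET is the interleaved-control-subtracted mean over the
one-minute analysis window:

    FRET = mean(ROI | LED on) − mean(ROI | LED off)

Each recording day (pre-treatment plus 1, 2, 3 h post-dose) is expressed
relative to its own hour-0 baseline:

    ΔFRET_t = 100 · (FRET_t − FRET_0) / FRET_0        [%]

and summarised by max ΔFRET, min ΔFRET, and the trapezoidal AUC
Σ (ΔFRET_A + ΔFRET_B)/2 · (t_B − t_A) over 0–3 h (%·h). An inhibitor spares
the sensor pool, so ΔFRET rises; an ionomycin-like activator drives it
negative. Cohorts are analysed with a two-way repeated-measures ANOVA
(time × treatment; REML mixed-model fallback for missing cells), one-way
ANOVA + Tukey HSD across doses, t-tests, and Pearson correlations, after the
histology exclusion rule (<100 EYFP+ neurons or off-target fibre) and the
matched-data inclusion rule.

The built-in simulator generates full frame streams from sensor kinetics
dS/dt = k_syn − (k_deg + k_cl·a(t))·S with Bateman drug pharmacodynamics,
photobleaching, common-mode motion artifacts and camera noise — with
closed-form oracles (e.g. ΔFRET_ss = 100·f/(1−f) for sustained inhibition f
at k_deg = 0) that the test-suite checks the whole pipeline against. See the
vignette in `vignettes/calpain-photometry.Rmd` for the model and the default
study conditions.

## Worked example

```r
library(photofret)
library(dplyr)

params <- sensor_params()
f <- inhibition_for_steady_state(params, target_pct = 30)  # 0.277
spec <- cohort_spec(
  n_animals = 8,
  treatments = list(drug_profile("vehicle"),
                    drug_profile("inhibitor", magnitude = f, dose = 2)),
  seed = 42
)
experiment <- simulate_cohort(spec, params) |> process_experiment()

experiment$summaries |> group_by(treatment) |>
  summarise(mean_max = mean(max_delta_fret), mean_auc = mean(auc))
#> # A tibble: 2 × 3
#>   treatment mean_max mean_auc
#>   <chr>        <dbl>    <dbl>
#> 1 inhibitor  12.5    28.1
#> 2 vehicle     0.0758  0.00293

tidy(rm_two_way_anova(experiment$delta_fret))
#> # A tibble: 3 × 5
#>   term           df_num df_den statistic  p_value
#>   <chr>           <dbl>  <dbl>     <dbl>    <dbl>
#> 1 hour                3     21    19774. 2.19e-36
#> 2 treatment           1      7    36655. 2.80e-14
#> 3 hour:treatment      3     21    26305. 1.10e-37
```

The inhibitor, calibrated so a sustained effect would raise ΔFRET by 30% at
steady state, produces a mean maximum ΔFRET of ~12.5% within the 3 h day
(onset and washout keep it below the asymptote), an AUC of ~28 %·h, and a
decisive treatment effect; vehicle stays at baseline. `autoplot(experiment)`
draws the group time courses.

Real recordings are analysed the same way from disk:

```r
experiment <- process_experiment("path/to/manifest.json")
write_results(experiment, "results/")
```

A thin command-line wrapper over these functions is in
`inst/scripts/photofret.R` (subcommands `simulate`, `validate`, `process`,
`stats`, `blot`).

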