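# plumetrack

Video-based measurement of the **impulse dispersion of exhaled aerosol
clouds** — how far the cohesive cloud expelled while speaking or playing a
wind instrument travels from the mouth before room convection takes over.
The package implements the full measurement chain used in studio studies of
infection-control measures for singers and wind players (such as soprano
recorder playing with and without protective devices), where subjects
inhale e-cigarette vapor as an aerosol proxy and the white cloud is filmed
against a black background by a side-view camera (frontal x, vertical z)
and a top-view camera (lateral y).

**For whom:** researchers in voice/wind-instrument aerosol studies and
bioimage analysts who need a tested, scriptable replacement for the
ad-hoc chain of image-editing, segmentation and spreadsheet steps such
studies typically use.

## What it computes

Per video frame the cloud is segmented by global thresholding (fixed or
per-frame Otsu with small-component removal), converted to metric extents
from the mouth origin via scale-bar calibration, and placed on a time axis
with *t* = 0 at the end of the task. Each directional extent series is
filtered by a 30-sample moving median and a cubic-spline interpolation
through every 5th sample. Across subjects the package reports, per task,
the **median and maximum** frontal distance `x_front` and lateral diameter
`y_diameter` at **0, 3 and 10 s** after task end, pointwise median curves
over time, and the **±0.1 m comparison markup** between tasks
(`higher` / `lower` / `comparable`, inclusive at |Δ| ≥ 0.1 m on 0.01
m-rounded values). For acoustics, long-term average spectra (LTAS:
512-point Hanning FFT, Welch-style power averaging, peak-normalized dB
with a −110 dB floor) compare the instrument's sound with and without
safety devices via per-bin averages and mean squared error.

A synthetic scenario generator renders two-view plume videos whose ground
truth is analytic — each direction follows
`d(t) = A(1 − exp(−(t + T)/τ))` during the task and `d(0) + v·t` after it —
so the whole pipeline is testable without studio footage (see the methods
vignette in `vignettes/`).

## Worked example

Three synthetic "subjects" playing the same task, measured end to end:

```r
library(plumetrack)
subjects <- lapply(1:3, function(i) {
  sc <- plume_scenario(
    expansion_params = list(
      x_front    = list(A = 1.00 + 0.06 * i, tau = 2,   drift = 0.010),
      y_diameter = list(A = 0.50 + 0.05 * i, tau = 2.5, drift = 0),
      z_up       = list(A = 0.45 + 0.03 * i, tau = 3,   drift = 0.005),
      z_down     = list(A = 0.25 + 0.03 * i, tau = 3,   drift = 0)
    ),
    noise_sd = 5, subject_id = paste0("S", i), task_id = "T3", seed = 200L + i)
  scene <- generate_plume_scenario(sc)
  track_dispersion(scene$side_view, scene$top_view,
                   scene$calibration$side, scene$calibration$top)
})
summarize_dispersion(subjects)
#>    task  dimension statistic timepoint_s value_m n_subjects
#> 1    T3    x_front    median           0    1.09          3
#> 2    T3    x_front   maximum           0    1.15          3
#> 3    T3    x_front    median           3    1.12          3
#> 4    T3    x_front   maximum           3    1.18          3
#> 5    T3    x_front    median          10    1.19          3
#> 6    T3    x_front   maximum          10    1.25          3
#> 7    T3 y_diameter    median           0    0.57          3
#> ...
```

The medians say the front of the cloud sits at 1.09 m from the mouth when
playing stops and creeps to 1.19 m ten seconds later (the scenarios drift
at 1 cm/s), while the lateral diameter stays at 0.57 m — distances a
seating plan can be checked against.

The bundled published summary table for the six recorder-study tasks
(T1 speaking … T6 suction funnel) validates the comparison markup:

```r
tbl <- recorder_dispersion_table()
marked <- mark_dispersion_table(tbl)   # T2-T3 vs T1, T4-T6 vs T3
head(marked[marked$task == "T6", c("statistic", "timepoint_s", "value_m",
                                   "reference_m", "difference_m", "mark")], 4)
#>    statistic timepoint_s value_m reference_m difference_m  mark
#> 49    median           0    0.65        1.06        -0.41 lower
#> 50    median           3    0.42        0.93        -0.51 lower
#> 51    median          10    0.39        1.01        -0.62 lower
#> 52   maximum           0    1.16        1.35        -0.19 lower
sum(marked$mark == tbl$printed_mark[tbl$task != "T1"])
#> [1] 60
```

All 60 printed bold/italic/unmarked annotations are reproduced: every
suction-funnel (T6) value is at least 0.1 m below unprotected playing,
confirming it as the only device that reduced dispersion in all
directions.

## Command line

A CLI covering every stage ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "plumetrack-cli.R", package = "plumetrack"))')" \
  simulate --out sim/ --seed 5
# then: preprocess / segment / track / smooth / summarize / ltas / ltas-mse
```

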