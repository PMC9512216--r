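---
title: "Measuring aerosol plume impulse dispersion from two-view video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring aerosol plume impulse dispersion from two-view video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

When a person speaks or plays a wind instrument, the exhaled air carries
aerosols — particles below 5 µm that stay airborne for hours and can carry
respiratory viruses. One way to characterize the immediate risk zone around
a player is *impulse dispersion*: how far the cohesive exhaled cloud
travels from the mouth under its own momentum, before room convection takes
over. In studio experiments this is made visible by having subjects inhale
e-cigarette vapor (particle size 250–450 nm, within the range of exhaled
aerosols) before each task; spotlit against a black background, the white
cloud is filmed by synchronized cameras — a side view whose image columns
carry the frontal x-direction and rows the vertical z-direction, and a top
view whose rows carry the lateral y-direction — and its extent is measured
frame by frame.

`plumetrack` implements that measurement chain as reusable, tested code:

1. **Input and preprocessing** (`load_frames`, `to_negative_bw`,
   `apply_exclusion_masks`): 8-bit grayscale frame stacks; optional
   negative conversion for parity with editing-software workflows; polygon
   exclusion masks for uncovered body parts, specular reflections and
   stray clouds (e.g. the cloud re-released at a suction-funnel outlet).
2. **Segmentation** (`segment_cloud`): global threshold (fixed or
   per-frame Otsu) plus removal of 8-connected components below a minimum
   area. All surviving components are treated as one cloud, since vapor
   escaping through the labium and the bell hole merges.
3. **Calibration and extent tracking** (`calibrate_view`,
   `extract_extents`, `align_to_task_end`, `merge_views`): metric scale
   bars give metres-per-pixel per image axis; extents are distances from
   the mouth origin — one-sided frontal distance `x_front`, vertical
   `z_up`/`z_down`, and the full lateral span `y_diameter`. Time zero is
   the end of the task, so the task itself occupies negative times.
4. **Temporal smoothing** (`moving_median`, `spline_smooth`): a 30-sample
   moving median followed by a cubic-spline interpolation through every
   5th sample removes segmentation outliers.
5. **Summaries** (`summarize_dispersion`, `median_curve`,
   `classify_vs_reference`, `report_differences`): cross-subject medians
   and maxima at 0, 3 and 10 s after task end, pointwise median curves,
   and the ±0.1 m comparison markup between tasks.
6. **Acoustics** (`compute_ltas`, `average_spectra`, `ltas_mse`): long-term
   average spectra (512-point Hanning FFT, −110 dB floor) of recordings
   with and without protective devices, and their mean squared error.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fps` | 25 | frames/s | broadcast-camera rate of the emulated studio setup |
| segmentation `threshold` | `"otsu"`, clamped at ≥ 50 | intensity | spotlit white-on-black footage is close to bimodal; the clamp keeps near-uniform background frames from segmenting noise |
| `min_component_area_px` | 20 | px | rejects isolated noise pixels without eroding the cloud |
| median `window` | 30 | samples (1.2 s) | the published smoothing choice for this workflow |
| spline `knot_stride` | 5 | samples (0.2 s) | interpolation through *every* point would smooth nothing; 0.2 s knots remove single-frame outliers while following the cloud dynamics |
| summary `timepoints_s` | 0, 3, 10 | s | the reporting convention for task-end, short-term and late dispersion |
| markup `tolerance_m` | 0.1 | m | differences below table precision ±0.1 m are treated as comparable |
| LTAS `nfft`, `hop`, floor | 512, 256, −110 | samples, dB | the speech-analysis convention used for such comparisons (Hanning window, Welch-style power averaging) |

## The synthetic world

No studio footage ships with this package, so every downstream stage is
verified against a synthetic generator (`plume_scenario`,
`generate_plume_scenario`) whose ground truth is analytic. Each
directional extent follows

$$d(t) = A\left(1 - e^{-(t + T)/\tau}\right), \quad t \in [-T, 0], \qquad
d(t) = d(0) + v\,t, \quad t > 0,$$

with task duration $T$ (default 8 s), asymptote $A$, time constant $\tau$
and post-task drift $v$: clouds grow while driven by exhalation and then
stagnate or drift slowly, which is the qualitative behaviour reported for
recorders and clarinets. The default asymptotes ($A_x = 1.08$ m,
$A_y = 0.58$ m diameter, $A_{z\uparrow} = 0.50$ m,
$A_{z\downarrow} = 0.30$ m with $\tau = 2\text{–}3$ s) are chosen once so
that the frontal extent reaches ≈ 1.06 m and the lateral diameter ≈ 0.57 m
at task end — the magnitudes reported for high-octave recorder playing.
Drifts of 0–0.01 m/s keep the post-task curve between stagnation and slow
expansion. The plume is rendered as a filled half-ellipse anchored at the
mouth pixel — the simplest shape whose directional maxima are analytically
known — at intensity 230 over background 20, with additive Gaussian noise
(default SD 5, clipped to [0, 255]) and optional bright artifacts (body
silhouette behind the mouth, floor reflection, detached funnel-release
cloud), each placed strictly inside declared exclusion polygons and
validated to be disjoint from any admissible plume position. All
randomness flows from one seed; output is bit-identical across runs.

What the generator does *not* emulate: turbulent wisps and diffuse cloud
edges, room convection, lens distortion, video compression, lighting
gradients, and real specular behaviour. A green synthetic test therefore
establishes that the *measurement chain* is correct (geometry,
calibration, timing, filtering, bookkeeping), not that segmentation would
be robust on arbitrary real footage. Scale bars are likewise emitted as
endpoint/length metadata rather than rendered into the frames — rendered
bright bars would themselves need exclusion masks in every scenario — so
the calibration round trip exercises the arithmetic, not bar detection.

## Numerical choices

* **Otsu plateau.** Between two well-separated intensity modes the
  between-class variance is flat; the implementation takes the first
  argmax, which lands just above the background mode. Any threshold on
  the plateau yields the same classification, so segmentation results are
  unaffected.
* **Spline end conditions.** "Cubic spline interpolation" is
  operationalized as interpolation through subsampled knots. End
  conditions are FMM (a cubic through the outermost four knots), not
  natural: natural end conditions force zero second derivative at the
  boundary and cannot reproduce a cubic trend at the series ends, whereas
  the FMM spline reproduces cubic polynomials exactly — a property the
  test suite checks to 10⁻⁹ relative error.
* **Median boundary rule.** The 30-sample window is centred; at the series
  boundaries it shrinks *symmetrically* (radius `min(i-1, n-i)`), so
  endpoints pass through unchanged. A one-sided shrink would drag boundary
  values toward the series interior by up to ~15 cm on a rising curve.
  Interior even windows span offsets −14…+15 with the even-count median
  defined as the mean of the central pair.
* **Smoothing error budget.** The raw measured series is quantized: floor
  quantization puts it within 1 px of truth, and the lateral *diameter*
  staircase moves in 2 px steps (the cloud grows symmetrically about the
  origin row). A C² spline through subsampled knots therefore cannot hug
  the staircase to 1 px at steep onsets; what it must not do is add
  distortion. The property tests assert: smoothed vs truth ≤ 1.5 px,
  smoothed vs raw input ≤ 2 px, and end-to-end recovery at the reporting
  timepoints ≤ 2 px.
* **Markup rounding.** Comparison marks are computed on values rounded to
  0.01 m (table precision) with an *inclusive* threshold
  (|difference| ≥ 0.1 m ⇒ marked): published tables mark a cell whose
  difference is exactly 0.10 m, which forces inclusivity.
* **Timepoint lookup** uses the nearest time-grid sample within half a
  frame — extents are frame-based measurements, so interpolating between
  frames would manufacture sub-frame information.
* **dB reference.** Each LTAS is normalized to its own maximum before
  clipping at −110 dB; the comparison of interest is spectral *shape*, and
  absolute levels are not preserved by typical recording chains anyway.
  Consequently `compute_ltas` is invariant to amplitude scaling.
* **Degenerate inputs.** Empty segmentation masks are valid (extent 0,
  not an error); digital silence yields a uniform −110 dB floor; a
  zero-amplitude scenario renders pure background and zero truth.

## Design decisions where the workflow was genuinely open

* `x_front` is taken from the side view only, even though the top view
  also sees x; the top-view value is kept as a QC attribute
  (`x_front_qc`). The lateral extent is reported as a *diameter* (total
  span), matching the published table shape; vertical statistics are
  computed identically but reported separately from the x/y table.
* Vertical and frontal distances are measured from the mouth origin, the
  declared starting point of dispersion.
* Masked pixels are filled with the modal intensity of the frame corners —
  a robust background estimate that guarantees masked regions can never
  segment as cloud, whatever threshold is chosen. Masking is idempotent
  and commutes with negative conversion when the fill is converted
  accordingly.
* The stray cloud released at the suction-funnel outlet is removed by a
  `funnel_release` exclusion polygon rather than by provenance tracking,
  mirroring how a human analyst distinguishes it.
* A missing view (as when a camera's footage must be discarded for
  reflections) is tolerated end to end: merged series simply lack that
  view's directions.

## Known limitations

Segmentation is global thresholding — adequate for spotlit
white-on-black studio footage, not for general scenes. No lens-distortion
correction or 3-D fusion is attempted; each direction comes from a single
calibrated view. The published headline distances derive from footage that
was never deposited, so the package validates against printed summary
values (the 60-cell comparison markup and two worked difference checks)
and against synthetic ground truth, not against the original recordings;
the published LTAS mean-squared-error values (4.7, 2.77, 5 dB²) are
likewise not reproducible without the original audio and are not targets.
Statistical inference is deliberately out of scope: with five subjects the
source study reported medians, maxima and marks, not tests.
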