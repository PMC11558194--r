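# casakit

Computer-assisted sperm analysis (CASA) for dark-field microscopy video, in
R. Compact LED-array microscopes image swimming sperm as bright head blobs
on a dark background; casakit turns such video into per-cell motility
records and population statistics, and ships a synthetic video generator so
every stage can be validated against exact ground truth — no patient
material required.

The pipeline is the classic CASA chain:

```
simulate ──► render ──► detect ──► track ──► analyze ──► compare
(ground     (dark-     (threshold, (gated    (VCL VSL    (CV, t-test,
 truth       field      8-conn      optimal   VAP LIN     ANOVA)
 tracks)     video)     blobs,      assign-   STR WOB)
                        3–30 µm²)   ment)
```

For a track of `M` head positions (µm) sampled `Δt` apart:

- **VCL** — curvilinear velocity, `Σⱼ |p_{j+1} − p_j| / ((M−1)Δt)`
- **VSL** — straight-line velocity, `|p_M − p_1| / ((M−1)Δt)`
- **VAP** — average path velocity: VCL of the 5-point moving-average path
- **LIN** = VSL/VCL, **STR** = VSL/VAP, **WOB** = VAP/VCL

Detection keeps only blobs with apparent areas in the closed 3–30 µm² band
(the human sperm-head range); tracking links centroids frame-to-frame by
globally cost-minimal gated assignment (Hungarian optimum, verified against
exhaustive enumeration). All stages take and return tidy data frames, so
calls chain with the pipe; fitted comparison objects have `tidy()` and
`glance()` methods and result tables have `autoplot()` methods.

The package also models the LED-array illumination geometry itself:
`classify_mode()` tells you whether a given LED pattern produces
bright-field, dark-field or mixed imaging for a given objective
(`α = atan(r/d)` per LED versus the acceptance half-angle `θ = asin(NA)`).

## Worked example

Simulate 20 cells for 1 s at 30 fps, render them as 8-bit dark-field video,
and run the full analysis:

```r
library(casakit)
library(dplyr)

tracks <- simulate_tracks(n_sperm = 20, duration_s = 1, fps = 30,
                          field_of_view_um = c(300, 300), seed = 7,
                          min_separation_um = 30)
optics <- optics_config(pixel_size_um = 1, frame_shape = c(300L, 300L))
video  <- render_video(tracks, optics, seed = 42)
video
#> <video_stack> 31 frames of 300 x 300 px, 30 fps, 1 um/px, 8-bit

result <- run_pipeline(video)
result
#> <casa_pipeline_result> 620 detections, 20 tracks

summarize_motility(result$motility, percent = TRUE)
#> # A tibble: 6 × 4
#>   parameter  mean    sd     n
#>   <chr>     <dbl> <dbl> <int>
#> 1 vcl_um_s   35.9  23.8    20
#> 2 vsl_um_s   20.8  16.1    20
#> 3 vap_um_s   23.4  17.3    20
#> 4 lin_pct    40.3  28.2    20
#> 5 str_pct    63.7  36.8    20
#> 6 wob_pct    51.2  22.4    20
```

All 20 simulated cells were recovered. The population swims at
35.9 ± 23.8 µm/s along its curvilinear path (the large SD reflects the 20%
immotile fraction of the default population model); linearity of 40%
indicates moderately curved paths, and WOB ≈ 51% means roughly half of the
raw path length is side-to-side head wobble rather than progress along the
average path.

Because the ground truth is known, we can validate the measurements the
same way trackers are compared on real material — pair each recovered track
with its true trajectory and compute the agreement CV and a t-test:

```r
starts <- result$tracks |> slice_min(frame, by = track_id, with_ties = FALSE)
truth0 <- tracks |> slice_min(frame, by = track_id, with_ties = FALSE)
pairing <- starts |>
  rowwise() |>
  mutate(true_id = truth0$track_id[which.min((truth0$x_um - x_um)^2 +
                                             (truth0$y_um - y_um)^2)]) |>
  ungroup() |>
  select(track_id, true_id)
paired <- pairing |>
  inner_join(result$motility, by = "track_id") |>
  inner_join(ground_truth_motility(tracks), by = c(true_id = "track_id"),
             suffix = c("_measured", "_truth"))

tidy(compare_methods(paired$vcl_um_s_measured, paired$vcl_um_s_truth, "vcl"))
#> # A tibble: 1 × 9
#>   parameter mean_a  sd_a mean_b  sd_b cv_percent t_statistic    df p_value
#>   <chr>      <dbl> <dbl>  <dbl> <dbl>      <dbl>       <dbl> <dbl>   <dbl>
#> 1 vcl         35.9  23.8   35.1  24.6       2.51      0.0956    38   0.924
```

Measured and true VCL agree to a 2.5% coefficient of variation — well below
the conventional 10% acceptance bar — with no significant difference
(p = 0.92).

Real video enters through `read_video()` (multi-page TIFF with a YAML
metadata sidecar) and TrackMate spot exports through `read_trackmate()`. A
thin command-line front end (`exec/casakit`) exposes `simulate`, `render`,
`detect`, `track`, `analyze`, `classify` and `pipeline` subcommands over
the same functions.

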