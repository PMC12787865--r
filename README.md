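# trayvol

Estimates how much food is on a plate from a single overhead camera view.

Cafeteria-monitoring systems capture each tray as it passes under a camera.
A detector finds the tray and the items on it, a prompt-based segmenter
produces per-item masks, and a monocular depth model turns the RGB frame
into a *relative* depth map — unitless values, normalized to roughly
\[0, 1\], with no metric scale. `trayvol` implements the geometry that turns
those ingredients into portion estimates, plus everything needed to validate
that geometry without any trained model in the loop.

## The method

Monocular depth models impose an artificial planar tilt across flat scenes
(a perspective artifact), which biases any naive depth summation. The
pipeline removes it and integrates what is left:

1. **Rim sampling.** The outer band of the plate mask (annulus of width
   `band_width`, food pixels excluded) is assumed physically flat and is
   sampled as support for the base plane.
2. **Base-plane fit.** Least squares (via SVD) fits
   `z = a·x + b·y + c` to the rim samples — the tilted "flat" reference.
3. **Correction.** `z_corr(x, y) = z_depth(x, y) − (a·x + b·y + c)`;
   negative values (below the plate surface) are clipped to zero.
4. **Volume integration.** Each pixel is a vertical prism of base area `s²`
   and height `z_corr`:
   `V = Σ_{(x,y) ∈ mask, z_corr > 0} z_corr(x, y) · s²`, in arbitrary units
   (a.u.) unless `s²` is metrically calibrated.
5. **Weight conversion.** A per-food-class density model `w = k·V`
   (optionally affine), fitted from calibration pairs, maps volume to grams.
6. **Robustness statistics.** Repeated passes of the same plate are
   summarized per rotation block by mean, sample SD, and the coefficient of
   variation `CV = 100·SD/mean`, plus a pooled frame-level CV.

Because real detector/segmenter/depth weights are not part of the package,
the perception stages are S3 contracts (`detect()`, `segment_item()`,
`estimate_depth()`) with a deterministic mock backend driven by synthetic
scenes whose ground truth (tilt plane, per-item closed-form volumes, exact
masks) is known — spherical caps, cones, and boxes standing in for rice and
chicken.

## Worked example

Simulate eight passes of a plate carrying a spherical-cap "rice" portion and
a box "chicken" portion on a tilted depth field, then run the full pipeline
through the mock backend:

```r
library(trayvol)

spec <- scene_spec(
  grid = c(512, 512), plane = c(0.03, -0.02, 0.25),
  items = list(
    shape_spec("spherical_cap", label = "rice",
               center = c(195, 256), radius = 51, height = 23),
    shape_spec("box", label = "chicken", center = c(327, 256),
               width = 82, length = 36, height = 26)))
scenes <- rotation_sequence(spec, seq(0, 315, by = 45))
dir <- file.path(tempdir(), "demo")
for (sc in scenes) write_scene(sc, dir)

backend <- mock_backend(dir)
res <- process_frame(backend, "rot001", pipeline_config())
res
#> <frame result 'rot001'> status: ok
#> # A tibble: 2 × 4
#>   label   frame_id volume n_pixels
#>   <chr>   <chr>     <dbl>    <int>
#> 1 rice    rot001   72017.     5713
#> 2 chicken rot001   76752.     2952
tidy(res$plane)
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 a       0.0300
#> 2 b      -0.0200
#> 3 c       0.250
```

The recovered plane is the injected tilt `(0.03, −0.02, 0.25)`, and the
volumes match the analytic ground truth (rice 72 015.78, chicken 76 752
a.u.) to rasterization error — 0.002 % for the cap, exact for the
axis-aligned box. Converting the chicken volume to grams with a density
model fitted from the bundled synthetic calibration table:

```r
pairs <- read_calibration_csv(system.file(
  "extdata", "synthetic_calibration_pairs.csv", package = "trayvol"))
model <- calibrate_density(dplyr::filter(pairs, food_class == "chicken"))
model
#> <density model 'chicken'> weight = 0.000890219 * V +0 g (proportional, n = 6, rms = 25.9 g)
estimate_weight(76752, model)
#> [1] 68.32608
```

Aggregating the eight rotations into a robustness report:

```r
seq_df <- tibble::tibble(frame_ref = sprintf("rot%03d", 1:8), block_id = 1:8)
report <- process_sequence(backend, seq_df, label = "chicken")
glance(report)
#> # A tibble: 1 × 5
#>   label   n_blocks n_frames mean_block_cv_percent global_cv_percent
#>   <chr>      <int>    <int>                 <dbl>             <dbl>
#> 1 chicken        8        8                    NA     0.00000000360
```

The chicken volume is invariant across rotations up to rasterization
(pooled CV ≈ 4 × 10⁻⁹ %; per-block CVs are `NA` because each of these
blocks holds a single frame). `autoplot(report)` draws the per-rotation
stability plot; `write_sequence_report(report, "out/")` persists the JSON
and CSV tables.

A thin command-line wrapper with subcommands `simulate`, `process-frame`,
`process-sequence`, `calibrate`, and `report` lives at `exec/trayvol`.

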