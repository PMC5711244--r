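# contourfit

Semiautomatic delineation of closed region boundaries in 2D grayscale
images — the contouring task at the heart of treatment planning for
image-guided radiation therapy (IGRT), where targets and organs at risk must
be outlined accurately but clinicians need to keep manual control.

`contourfit` is for users and pipeline authors who have a *rough* closed
boundary (hand-drawn, or produced by any upstream segmentation) and want it
turned into an accurate, smooth, subpixel contour with minimal interaction:

1. **Control-point allocation** — the boundary's arc length *L* fixes the
   number of uniformly spaced control points: 6 for *L* < 30 px, 10 for
   30–150 px, 20 for 150–200 px, 30 for *L* ≥ 200 px (never more than 30).
2. **Hermite curve fitting** — the control points are interpolated by a
   closed piecewise Hermite cubic
   *P(s) = h₁(s)P₀ + h₂(s)P₁ + h₃(s)u₀ + h₄(s)u₁* with Catmull–Rom tangents
   *uᵢ = (Pᵢ₊₁ − Pᵢ₋₁)/2*, sampled at Δs = 0.1 (ten points per segment).
   Moving one control point (`move_control_point()` / `revise`) changes only
   the four adjacent segments — revision is local.
3. **Subpixel refinement** — fully automatic, single pass, no iteration:
   every curve point is shifted along its local normal (total-least-squares
   line through the point and its two neighbors, rotated 90°) to the
   position of maximum Gaussian-derivative gradient magnitude within ±*d*
   pixels, searched at Δd = 0.1 px spacing with bilinear interpolation of
   the magnitude map.

A synthetic phantom generator with analytic ground truth, contour accuracy
metrics (mean boundary distance, Hausdorff, Dice) and a minimal Kass–Witkin
active-contour baseline are included, so the whole pipeline is testable
without external data.

## Worked example

```r
library(contourfit)

# the validation phantom: black disc, radius 85 px, centered in 256 x 256,
# additive Gaussian noise (sd 10 on the 0-255 scale)
scene <- make_noisy_disc(noise_sigma = 10, seed = 1)

# stand-in for an imprecise hand-drawn boundary: the true circle perturbed
# by smooth normal displacements of up to 1 px
init <- perturb_contour(scene$truth_contour, amplitude = 1, seed = 2)

res <- delineate(scene$image, init, run_config(sigma = 1, d = 2),
                 verbose = TRUE)
#>   boundary_length_px     535.232
#>   n_input_points         535
#>   n_control_points       30
#>   n_curve_points         300
#>   n_refined_points       300
#>   sigma                  1
#>   d                      2
#>   delta_d                0.1
#>   delta_s                0.1
#>   max_displacement_px    1

mean_boundary_distance(init, scene$truth_contour)
#> [1] 0.2980998
mean_boundary_distance(res$refined, scene$truth_contour)
#> [1] 0.1863739
contour_error_report(res$refined, scene$truth_contour, shape = c(256, 256))
#> <contour_error_report> mean |d| = 0.1864 px, Hausdorff = 0.4963 px, Dice = 0.9985, n = 300
```

Reading the numbers: the ~535-px boundary gets the maximum 30 control
points; at Δs = 0.1 the fitted closed curve has 30/0.1 = 300 samples. The
initial contour sits ~0.30 px from the true circle on average; after one
refinement pass the mean error drops to ~0.19 px — below pixel resolution —
with every point having moved at most *d* = 2 px, and the enclosed region
overlaps the true disc with Dice 0.9985.

## Command line

A thin `Rscript` front end ships in `inst/scripts/contourtool`:

```sh
Rscript inst/scripts/contourtool simulate  --out-image disc.png --out-truth truth.json --seed 1
Rscript inst/scripts/contourtool delineate --image disc.png --contour init.json --out refined.json
Rscript inst/scripts/contourtool metrics   --test refined.json --truth truth.json --rows 256 --cols 256
```

Subcommands: `simulate`, `delineate`, `revise`, `refine`, `snake`,
`metrics`. Flags override an optional `--config file.yaml`. Contours are
JSON (`{"closed": true, "points": [[x, y], ...]}`) or `x,y` CSV; images are
PNG/TIFF (or CSV matrices); coordinates are 0-based with x = column,
y = row.

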