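# sofitrend

Photodestruction correction for super-resolution optical fluctuation
imaging (SOFI) by per-pixel Whittaker smoothing.

## The problem

SOFI turns a sequence of fluorescence images of independently *blinking*
emitters into a super-resolved image by computing temporal (cross-)
cumulants of the pixel intensity traces. The method assumes the emitters'
dynamics are stationary and independent. Photobleaching violates both: it
makes the signal of *all* emitters decay together, which injects spurious
correlations into the cumulants — bright artifacts and haze that do not
reflect the underlying structure. The standard workaround, computing
cumulants on short batches of frames and averaging, only partially
suppresses the effect, especially when bleaching is fast.

`sofitrend` removes the slow trend before the cumulant analysis. Each
detector pixel's trace `y` (length `n` frames) is fit by Whittaker
smoothing — the penalized least squares problem

```
min over mu:  ||y − mu||² + λ ||D mu||²
```

where `D` is the (n−d)×n matrix of d-th order finite differences (d = 2
throughout) and `λ` the smoothing parameter. The fit solves the banded
system `(I + λ DᵀD) mu = y`, factored once per `λ` and reused for all
pixels. The smooth fits capture photodestruction and other slow effects;
the residual `y − mu` keeps only the fast blinking and is what the SOFI
cumulants are computed on. `λ` is selected automatically for the image in
its entirety by the V-curve: over a log-spaced grid, the distance between
consecutive points of the (log residual norm, log penalty norm) curve is
minimized — no tuning, no noise estimate.

The package provides, as first-class tested components:

* `smooth_trace()` / `smooth_matrix()` / `select_lambda_vcurve()` /
  `detrend_stack()` — the smoother and automatic parameter selection;
* `second_order_crosscumulant()` / `sofi_batched()` / `sofi_pipeline()` —
  second-order SOFI on the 2×-refined virtual-pixel grid, plus the
  batching baseline;
* `sofi_sim_config()` / `simulate_dataset()` — a blinking-fluorophore
  simulator (continuous-time Markov chain photophysics, Gaussian PSF,
  Poisson background, EMCCD camera, mono-exponential photodestruction);
* `snr_from_repetitions()` / `sofi_rmsd()` / `compute_reference()` /
  `evaluate_methods()` — the SNR/RMSD protocol comparing correction
  methods over repeated simulations;
* TIFF/CSV/JSON I/O (`read_stack()`, `write_stack()`, …) and a
  command-line front end (`inst/scripts/sofitrend.R`) with `smooth`,
  `sofi`, `simulate` and `evaluate` subcommands.

## Worked example

Simulate a fast-bleaching acquisition (survival time 1.1 s), remove the
trend with automatic smoothing, and compute the second-order SOFI image:

```r
library(sofitrend)

cfg <- sofi_sim_config(fov_pixels = c(16, 16), n_frames = 300,
                       n_fluorophores = 5000, tau_bleach_s = 1.1, seed = 1)
sim <- simulate_dataset(cfg)
sim
#> Simulated SOFI dataset: 16 x 16 px, 300 frames, 5000 emitters

det <- detrend_stack(sim$stack)      # V-curve picks lambda
det
#> Trend-corrected stack: 16 x 16 pixels, 300 frames (lambda = 1.122e+06)

img <- second_order_crosscumulant(det$corrected, source = "trend_corrected",
                                  lambda = det$lambda)
img
#> Second-order SOFI image (trend_corrected): 31 x 31 virtual-pixel grid
#>   value range [-2.396e+04, 3.57e+07]
#>   Whittaker lambda: 1.122e+06
```

The selected `λ ≈ 1.1e6` is stiff: over 300 frames the fit can follow the
bleaching decay but not the frame-to-frame blinking. The corrected stack is
real-valued (negative excursions are genuine and kept), and the 31 × 31
output interleaves physical pixels (trace variances) with virtual pixels
(neighbor covariances). `autoplot(img)` displays it; `autoplot(det$vcurve)`
shows the V-curve with the chosen minimum.

Comparing correction methods over repeated simulations:

```r
ev <- evaluate_methods(1.1, n_repetitions = 8,
                       config = sofi_sim_config(fov_pixels = c(16, 16),
                                                n_frames = 300,
                                                n_fluorophores = 5000),
                       n_ref_reps = 5, n_ref_frames = 500, seed = 7)
tidy(ev)
#> # A tibble: 3 × 7
#>   tau_bleach_s method    n_reps   snr   rmsd   lambda  seed
#>          <dbl> <chr>      <dbl> <dbl>  <dbl>    <dbl> <dbl>
#> 1          1.1 none           8  1.04 0.0285      NA      7
#> 2          1.1 batch          8  1.23 0.0251      NA      7
#> 3          1.1 whittaker      8  1.32 0.0238 1412538.     7
```

Under fast photodestruction the trend-corrected analysis has the highest
signal-to-noise ratio across repetitions and the lowest deviation from the
bleach-free reference — ahead of both the uncorrected analysis and 50-frame
batching.

The command-line interface wraps the same functions:

```sh
Rscript inst/scripts/sofitrend.R simulate config.yaml -o stack.tif --seed 1
Rscript inst/scripts/sofitrend.R sofi stack.tif --mode whittaker -o sofi.tif
```

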