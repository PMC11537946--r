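# octamorph

Quantitative characterization of paired en-face OCTA projection maps.

When two arms of OCT-angiography images exist for the same eyes — a
device-acquired reference ("GT") and a comparison arm such as a
GAN-translated reconstruction ("TR") — the question is whether the
comparison arm preserves the vascular biomarkers clinicians measure.
`octamorph` answers it with:

- **Vascular morphometry** per image, from binarization,
  centerline skeletonization, branch decomposition and sub-pixel
  contour extraction:
  - BVD, blood vessel density = vessel area / total area;
  - BVC, blood vessel caliber = vessel area / centerline length (px);
  - BVT, blood vessel tortuosity = mean over branches of
    geodesic / euclidean endpoint distance (1 = straight);
  - VPI, vessel perimeter index = boundary contour length / vessel
    area (1/px).
- **Image quality** per GT–TR pair and per cohort: SSIM, PCQI (patch
  contrast quality index) and the Fréchet distance between embedded
  image sets (a download-free deterministic embedding is the default).
- **Cohort statistics**: per-(group, arm, FoV) mean ± SD tables and
  two-tailed TR-vs-GT t-tests per feature (Welch and paired, both
  reported), with sentinel handling and exclusion logging.
- **A seeded synthetic cohort generator** — stochastic branching
  random-walk vasculature plus a parametric translation-artifact model
  (blur, capillary dropout, caliber jitter/bias, contrast drift,
  noise) — so the entire pipeline is testable without clinical data.

Everything is tibble-in / tibble-out and pipe-friendly; fitted reports
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(octamorph)

out <- file.path(tempdir(), "demo")
report <- run_pipeline(out, config = run_config(master_seed = 1L))
glance(report)
#> # A tibble: 1 × 5
#>   n_groups n_tests n_significant n_exclusions config_hash
#>      <int>   <int>         <int>        <int> <chr>
#> 1        2       4             2            0 951973a35890119a45f44d3783a2da06

dplyr::filter(tidy(report), method == "welch")
#> # A tibble: 4 × 8
#>   fov   feature method       t    df             p     n significant_at_0_05
#>   <chr> <chr>   <chr>    <dbl> <dbl>         <dbl> <int> <lgl>
#> 1 3mm   bvd     welch    0.854  18.0 0.404            10 FALSE
#> 2 3mm   bvc     welch   11.8    14.6 0.00000000727    10 TRUE
#> 3 3mm   bvt     welch    0.908  17.3 0.376            10 FALSE
#> 4 3mm   vpi     welch  -10.1    16.4 0.0000000191     10 TRUE
```

The demo cohort is two groups of five subjects with a moderate
degradation on the TR arm (1-px blur, 15% capillary dropout, 10%
caliber jitter, 2% pixel noise). The t-test table reads as in the
clinical use case: density and tortuosity survive this degradation
(p ≈ 0.4, no significant TR-vs-GT difference), while caliber and
perimeter index shift significantly — blur and dropout change apparent
vessel width and boundary complexity long before they change where
vessels are. The quality tables from the same run report mean
SSIM 0.631, mean PCQI 0.702 and a set-level Fréchet distance of 3.75
between arms.

Every output CSV is stamped with the package version, configuration
hash and master seed; rerunning with the same seed reproduces the files
byte-for-byte.

Lower-level entry points compose with the pipe:

```r
manifest <- make_cohort(demo_groups(), master_seed = 1L, out_dir = out)
features <- quantify_cohort(manifest)        # one row per image
quality  <- quality_pairs(manifest)          # SSIM/PCQI per pair
fid      <- quality_fid(manifest)            # Fréchet distance per FoV
build_report(manifest, features, quality, fid)
autoplot(features)                           # per-group boxplots
```

See `vignettes/octa-characterization.Rmd` for the measurement model,
the numerical choices (junction detection, geodesic length estimation,
perimeter estimation) and the calibration study behind the defaults.

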