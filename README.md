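# riglocate

Per-cell quantification of a cytosolic innate-immune receptor's
subcellular distribution from multi-channel fluorescence microscopy,
plus the qPCR readouts that accompany such experiments.

The scientific question this tooling serves: does an RNA-sensing
receptor (RIG-I) accumulate at the mitochondrial network while it
signals through its mitochondrial adaptor (MAVS), or does it stay
uniformly distributed? Answering that from images needs statistics that
are insensitive to expression level and illumination. The package is
aimed at cell biologists quantifying confocal data and at anyone who
needs a reproducible, testable reimplementation of these common
FIJI-style measurements.

## What it computes

* **Organelle colocalization ratio** — for each cell, the mean receptor
  signal on an organelle mask `M` divided by its mean in a cytosolic
  ring a fixed physical distance away:

  `ratio = mean(S | M) / mean(S | ring)`, with
  `ring = {p : r < d(p, M) <= 2r}` (default `r` = 300 nm), where
  `d(·, M)` is the exact Euclidean distance transform. The shell
  `{d <= r}` is an excluded buffer. A ratio of 1 means no enrichment.
* **Receptor bodies (puncta)** — connected regions at least 1 µm in
  equivalent diameter and at least 10× brighter than the mean cytosolic
  signal, counted per cell and scored for colocalization with a second
  channel.
* **Line profiles** (nucleus → membrane, bilinear sampling) and a
  uniformity CV.
* **Nuclear translocation index** for a transcription factor:
  `mean(nucleus) / mean(cytosol)`.
* **ΔΔCt fold induction** (`2^(−ΔΔCt)`, normalized to a reference gene
  and a mock condition) and **absolute copies per cell** via a
  log-linear standard curve `Ct = b + m·log10(copies)` with efficiency
  `10^(−1/m) − 1` and limit-of-detection handling.
* **Group statistics** — one-way ANOVA across conditions plus pairwise
  t-tests against a reference, the convention for per-cell ratio
  figures.
* A **synthetic-cell / synthetic-qPCR simulator** with exact ground
  truth, used to validate all of the above end to end.

## Worked example

Simulate a mock cohort (enrichment ρ = 1) and a stimulated cohort
(ρ = 2.5), run the full measurement chain — organelle mask → ring mask →
per-cell ratio — and compare groups:

```r
library(riglocate)
library(dplyr)

set.seed(1)
seeds <- matrix(sample.int(2147483646, 24), nrow = 12)
cells <- bind_rows(lapply(seq_len(24), function(i) {
  rho <- if (i <= 12) 1 else 2.5
  p <- sim_params(image_shape = c(96L, 96L), cell_radius_um = 3.5,
                  nucleus_radius_um = 1.3, organelle_filaments = 3,
                  enrichment_rho = rho, seed = seeds[[i]])
  s <- simulate_cell(p, channels = c("receptor", "organelle"))
  roi <- cell_roi(sprintf("cell_%02d", i), s$truth$cell_mask,
                  s$truth$nucleus_mask)
  inner <- build_organelle_mask(get_channel(s$image, "organelle"), roi)
  rings <- build_ring_mask(inner, roi, dilation_radius_nm = 300,
                           pixel_size_nm = p$pixel_size_nm)
  coloc_ratio(get_channel(s$image, "receptor"), rings, roi,
              condition = if (rho == 1) "mock" else "stimulated")
}))

compare_groups(cells, reference = "mock")
#> <group_comparison> one-way ANOVA F = 1933, p = 6.209e-23 (ref: mock)
#> # A tibble: 2 × 4
#>   condition      n mean_ratio sd_ratio
#>   <chr>      <int>      <dbl>    <dbl>
#> 1 mock          12       1.03   0.0252
#> 2 stimulated    12       2.22   0.0906
#> pairwise vs reference:
#> # A tibble: 1 × 4
#>   condition  estimate statistic  p_value
#>   <chr>         <dbl>     <dbl>    <dbl>
#> 1 stimulated     1.19      44.0 6.21e-23
```

The mock cohort sits at ratio ≈ 1 (no enrichment); the stimulated cohort
is clearly above it. The measured 2.22 is below the true ρ = 2.5 because
PSF blur bleeds organelle-proximal signal into the ring — the bias is
always toward 1, never past the truth, so enrichment calls are
conservative.

The qPCR side in two lines — a treated condition whose target Ct drops
from 28 to 21 against a flat reference gene is a 2^7 = 128-fold
induction:

```r
ct <- tibble::tibble(condition = rep(c("Mock", "SLR14"), each = 2),
                     gene = rep(c("IFNB", "ACTB"), 2),
                     replicate = 1, ct = c(28, 18, 21, 18))
delta_delta_ct(ct, "IFNB")$by_condition
#> # A tibble: 2 × 4
#>   condition delta_ct delta_delta_ct  fold
#>   <chr>        <dbl>          <dbl> <dbl>
#> 1 Mock            10              0     1
#> 2 SLR14            3             -7   128
```

Fitted and grouped results have `tidy()` / `glance()` methods and
`autoplot()` figures; `run_pipeline()` orchestrates
simulate → segment → measure → statistics runs with a reproducible JSON
manifest, and `inst/scripts/riglocate.R` exposes the same operations as
a command line.

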