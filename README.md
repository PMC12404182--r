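# thermalscape

Climate-vulnerability analysis for mountain lake landscapes from monthly
air temperature. `thermalscape` is for landscape ecologists and
limnologists who have watershed point locations (lake sites with region
labels and elevations) and monthly mean air-temperature series — the
resolution of downscaled climate archives — and want to know *where* a
warming landscape is warming fastest and *which* watersheds are most
exposed.

The pipeline:

1. **Heat accumulation.** Annual growing and killing degree days per
   watershed via the monthly-expander degree-day sum
   `DD = Σ_t (T_t − T_0), T_t > T_0`, with every day of a month assigned
   that month's mean. GDD uses a 0 °C base; KDD uses a region-specific
   threshold, the 90th percentile of the region's pooled historical
   monthly means.
2. **Velocity of change.** Per region, a REML linear mixed model
   `y_it = (β₀ + b₀ᵢ) + (β₁ + b₁ᵢ)·t + ε` on `ln(GDD + 1)` with year fixed
   and watershed random on intercept and slope. Each watershed's total
   slope `β₁ + b₁ᵢ` is its velocity of change; marginal/conditional
   pseudo-R², velocity–elevation Pearson correlations and a one-way ANOVA
   across regions summarise the fits.
3. **Vulnerability tiers.** Per region, exact 1-D k-means (dynamic
   programming over contiguous partitions) on ln-transformed mean
   historical GDD, a priori constrained to three clusters labelled cold /
   transitional / hot by ascending centre.
4. **Projection.** A linear discriminant per region on the standardised
   feature predicts tier membership (with posteriors) for future
   period climatologies, yielding membership and percent-change tables
   and killing-degree-day change summaries.

A synthetic landscape generator — seasonal cycle, elevation lapse,
elevation-dependent warming trend, Gaussian noise, stepwise projection
offsets — carries known true slopes so the whole chain is validated by
parameter recovery. Real extracts can be supplied through the same CSV
schemas.

## Worked example

```r
library(thermalscape)
library(dplyr)

res <- run_pipeline(seed = 1, quiet = TRUE)   # demo: 2 regions x 50 watersheds x 40 years
res
#> <pipeline_result> 100 watersheds, 2 regions, 40 historical years, 3 periods
#> Pooled membership:
#> # A tibble: 4 × 9
#>   region time_period     n pct_cold pct_transitional pct_hot chg_cold
#>   <chr>  <chr>       <int>    <dbl>            <dbl>   <dbl>    <dbl>
#> 1 all    historic      100       29               34      37     NA
#> 2 all    2011-2040    100       22               32      46    -24.1
#> 3 all    2041-2070    100       13               32      55    -55.2
#> 4 all    2071-2100    100        3               35      62    -89.7
```

The pooled hot tier grows from 37% of watersheds in the historical window
to 62% by end of century, while the cold tier collapses by ~90% — the
tier shares in each row sum to 100, and the bold-style change columns are
computed on unrounded shares.

```r
glance(res$fits) %>%
  select(region, fixed_slope, r2_marginal, r2_conditional, singular)
#> # A tibble: 2 × 5
#>   region fixed_slope r2_marginal r2_conditional singular
#>   <chr>        <dbl>       <dbl>          <dbl> <lgl>
#> 1 r1         0.00214     0.00424          0.992 FALSE
#> 2 r2         0.00223     0.0303          0.920 FALSE

res$velocity_tests$pearson
#> # A tibble: 2 × 4
#>   region pearson_r  p_value     n
#>   <chr>      <dbl>    <dbl> <int>
#> 1 r1        -0.989 3.98e-41    50
#> 2 r2        -0.992 4.55e-45    50
```

Both regions trend upward on the `ln(GDD+1)` scale (positive fixed
slopes); nearly all response variance is explained once watershed random
effects are included (conditional R² 0.92–0.99), and velocity correlates
strongly negatively with elevation — low-elevation watersheds are warming
fastest, by construction of the generator and as recovered by the model.

```r
res$kdd_change
#> <kdd_change_summary>
#> # A tibble: 2 × 4
#>   region mean_kdd_historic mean_kdd_future pct_change
#>   <chr>              <dbl>           <dbl>      <dbl>
#> 1 r1                  96.6            292.       202.
#> 2 r2                  75.1            281.       274.
#> Across regions: 201.8% to 274.1% (mean 238.0%)
```

Mean killing degree days roughly triple by end of century under the
default warming offsets. `run_pipeline(cfg, out_dir = "...")` additionally
writes every stage's CSV plus a `manifest.json` with row counts and
checksums; outputs are byte-identical under a fixed seed.

Plotting helpers: `plot_gdd_trends(res$fits)`,
`plot_velocity_elevation(res$velocities)`,
`plot_membership(res$membership)`; fitted objects support `tidy()` and
`glance()`.

A command-line driver with stagewise subcommands (`simulate`,
`degree-days`, `velocity`, `classify`, `project`, `report`, `run-all`)
ships in `inst/cli/thermalscape`.

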