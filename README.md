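# seasonstruct

Seasonal structural stability of forest canopies from UAV-LiDAR, and its
link to diversity and overyielding in tree diversity experiments.

`seasonstruct` is for forest ecologists and remote-sensing scientists who
survey experimental tree communities repeatedly through a growing season
with drone LiDAR and want to connect what the canopy does over time to what
the trees produce. It implements, end to end:

* **Point-cloud conditioning** — height normalization against a
  grid-minimum ground surface, clipping to plot polygons with a −0.5 m
  buffer (an effective 81 m² analysis region on 10 m × 10 m plots),
  statistical outlier removal (k = 30 neighbours, 97.5 % quantile, applied
  to vegetation points above 0.25 m only), and 1 cm voxel decimation.
* **Structural metrics per plot and survey**:
  * `HH_cv` — coefficient of variation of a 0.1 m digital canopy model,
    the horizontal heterogeneity of the canopy surface;
  * `FC` — fractional plant cover,
    `FC = Σ (1/return_number) / n_pulses` over returns more than 0.25 m
    above ground;
  * `d_D` — a box-counting fractal dimension computed with Hill diversity:
    at each voxel edge size *S*, the occupancy proportions *p·* give
    `qD = (Σ pᵢ^q)^(1/(1−q))`, and `d_D` is the standardized-major-axis
    slope of `log D` on `log(1/S)` (default q = 0.999, twelve log-spaced
    scales over 0.1–2.25 m).
* **Seasonal structural stability** — `SS = x̄/σ`, the inverse coefficient
  of variation of each metric across the season's surveys (eight by
  default, DOY 100–297).
* **Ground-based productivity** — conoid/conoid-frustum stem volumes from
  height, root-collar diameter and DBH; annual wood productivity (AWP,
  m³ yr⁻¹ ha⁻¹); the net biodiversity effect
  `NBE = AWP_plot − Σ AWPᵢ pᵢ` and its exact Loreau–Hector partition into
  complementarity and selection effects (`NBE = CE + SE`).
* **Diversity and variability** — Hill diversity (q = 0) for taxonomic,
  phylogenetic (Faith PD) and functional (total trait distance)
  dimensions, and Helmus-type species variability
  `PSV = 1 − mean off-diagonal correlation` on three tree types: the
  phylogeny, a UPGMA functional-trait dendrogram, and a unit-step
  taxonomic-distinctness tree.
* **The statistical layer** — per-DOY cross-sectional regressions, mixed
  models with plots nested in blocks and a metric × DOY interaction, and a
  structural equation model with latent Diversity and Variability factors
  (three indicators each) explaining SS and NBE.
* **A synthetic forest-scene generator** — species pool with a
  two-clade (evergreen/deciduous) ultrametric phylogeny and partially
  phylogenetically autocorrelated traits, a replicated block design with
  richness levels 1–12, two annual inventories with an injected,
  variability-scaled complementarity effect on growth, and per-survey
  point clouds with double-sigmoid leaf phenology, multi-return pulses,
  ground returns and sky-noise outliers — so every stage above is testable
  without any field data.

## A worked example

```r
library(seasonstruct)

pool   <- generate_species_pool(n_species = 12, n_evergreen = 4, seed = 1)
design <- generate_design(pool, n_blocks = 3, plots_per_richness = 2, seed = 1)
inv    <- generate_inventories(design, pool, complementarity = 0.5, seed = 1)

plot_id <- design$plots$plot_id[30]          # a 2-species mixture
cloud <- simulate_point_cloud(
  inv$inventory[inv$inventory$plot_id == plot_id, ],
  pool, doy = 215, density = 100, seed = derive_seed(1, plot_id, 215))
cond <- condition_cloud(cloud, design$polygon)

canopy_height_cv(cond)   # 0.709
fractional_cover(cond)   # 0.756
fractal_dimension(cond)  # 1.918

pt <- productivity_table(inv$inventory[inv$inventory$interior, ], design)
pt[pt$plot_id == plot_id, c("awp", "awp_expected", "nbe", "ce", "se")]
#    awp      awp_expected  nbe    ce    se
#    19.82    9.07          10.75  10.57 0.18
```

The mid-season mixture intercepts three quarters of the pulses
(`FC = 0.756`), fills space with a fractal dimension of 1.92 (between a
surface and a volume), and overyields by 10.75 m³ yr⁻¹ ha⁻¹ relative to
its monoculture expectation — almost all of it (10.57) complementarity
rather than selection, as expected when the generator boosts growth in
proportion to functional variability.

Fitting the SEM on a simulated analysis table:

```r
sim <- simulate_analysis_table(150, seed = 42)
fit_sem(sim$plot_table, "ss_dD")
#> SEM (ML, n = 150, SS metric = ss_dD, converged)
#> Standardized paths:
#>         from  to    std     se      p
#>    Diversity  ss 0.2803 0.0691 0.0001
#>  Variability  ss 0.6470 0.0730 0.0000
#>           ss nbe 0.6847 0.0904 0.0000
#>  Variability nbe 0.0716 0.0888 0.4198
#>    Diversity nbe 0.1049 0.0658 0.1111
#> R2: SS = 0.616, NBE = 0.633;  latent correlation = 0.327
```

The full chain — simulate, condition, measure, stabilize, partition,
model — runs from a single call:

```r
report <- run_pipeline(default_config(seed = 1), out_dir = "out/")
```

or from the shell via the thin wrapper
`Rscript inst/scripts/seasonstruct.R --config cfg.yaml --out out/`.

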