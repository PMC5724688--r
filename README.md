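# canophot

Multiscale canopy photosynthesis simulation: from photosystem antenna size to
daily field-level CO2 uptake.

`canophot` is for crop-physiology modellers asking a specific engineering
question: *if a cereal leaf held less chlorophyll — by truncating the
light-harvesting antenna of its photosystems — would the canopy as a whole
fix more carbon, and at what nitrogen cost?*  The package builds a 3D stand,
ray-traces its diurnal light, distributes nitrogen down the canopy,
lets every leaf re-optimize its protein portfolio for its own light, and
integrates mechanistic leaf photosynthesis to canopy totals.

## The model in brief

- **Canopy**: parametric triangle-mesh stand (plants on a grid, tiller whorls
  of ranked blades with parabolic droop); LAI, leaf angle and plant height
  are scalable factors.  The plot is horizontally periodic, so a small stand
  represents an extended field.
- **Light**: solar geometry + clear-sky direct/diffuse split, then forward
  Monte-Carlo ray tracing with deterministic energy splitting at each facet
  (absorbed / reflected / transmitted per leaf optics, Lambertian
  scattering, bounded bounces).  The energy ledger
  `leaf + soil + escaped + residual = incoming` closes to machine precision.
  Canopy light statistics include the Beer's-law extinction coefficient *k*
  fitted on cumulative LAI: `I(L) = I0 e^(-kL)`.
- **Chlorophyll bookkeeping**: per unit PSII with cores of 37 (PSII) and 95
  (PSI) chlorophylls, 14 per LHC unit and [PSI]/[PSII] = 1.4,

      Chl = PSII (37 + 14 n1) + PSI (95 + 14 n1) = PSII (170 + 33.6 n1),

  where `n1` is the antenna size in LHC units — the dial the whole package
  studies.  Leaf absorbance follows a saturating function of chlorophyll.
- **Nitrogen profile**: `N_LA = (N_LA^fl − n_b)(I_l / I_lfl)^b + n_b` with
  `b = β · GAI^(−α)` — leaf nitrogen tracks the daily light profile between
  the flag-leaf and basal values.
- **Leaf**: seven protein pools (Rubisco, other Calvin-cycle enzymes,
  electron transport chain + ATPase, PSII, PSI, LHCII, LHCI) set capacities
  through `Vmax = kcat · c`; a PSII excitation-partition submodel divides
  absorbed photons among photochemistry, regulated heat and fluorescence;
  assimilation is `A = min(Wc, Wj) − Rd` with Farquhar CO2/O2 kinetics.
- **Acclimation**: each leaf splits its photosynthetic nitrogen between
  capacity and light capture to maximize daily carbon gain of its fitted
  nonrectangular-hyperbola light response (`P_max`, φ, θ, `R_d`), using
  calibrated linear pool–parameter relations.
- **Scenarios**: chlorophyll multipliers (0.4–1.2×) via the antenna route,
  with freed nitrogen either leaving the leaf (`lhc_only`) or reinvested in
  all other pools at constant total N (`constant_total_n`); architecture ×
  latitude robustness sweeps; NUE = daily A_c per g photosynthetic N.

## Worked example

```r
library(canophot)

cfg <- default_config()        # 3x3-plant rice-like stand, LAI ~4.6,
                               # Shanghai 31 N, day 235, 0.5 h steps
res <- run_pipeline(cfg, seed = 1)
res
#> <canopy_result> chl x1.00 (lhc_only): A_c 1.4978 mol m-2 d-1, N 4.423 g m-2, NUE 0.3386
```

The stand fixes ~1.50 mol CO2 per m2 ground per day and holds 4.42 g of
photosynthetic nitrogen per m2 ground, so each gram of invested N returns
0.34 mol CO2 daily.  Sweeping chlorophyll at both nitrogen strategies:

```r
sw <- run_chl_sweep(cfg, multipliers = c(0.4, 0.6, 0.8, 1.0, 1.2), seed = 1)
as.data.frame(sw)
#>    multiplier         strategy   a_c canopy_n    nue d_a_c_pct d_nue_pct
#> 1         0.4         lhc_only 1.532    3.956 0.3874    2.3130   14.3907
#> 2         0.6         lhc_only 1.541    4.110 0.3751    2.9054   10.7541
#> 3         0.8         lhc_only 1.504    4.266 0.3526    0.4388    4.1284
#> 4         1.0         lhc_only 1.498    4.423 0.3386    0.0000    0.0000
#> 5         1.2         lhc_only 1.490    4.580 0.3255   -0.4920   -3.8972
#> 6         0.4 constant_total_n 1.546    4.423 0.3495    3.1956    3.1956
#> 7         0.6 constant_total_n 1.548    4.423 0.3500    3.3666    3.3666
#> 8         0.8 constant_total_n 1.511    4.423 0.3417    0.8936    0.8936
#> 9         1.0 constant_total_n 1.498    4.423 0.3386    0.0000    0.0000
#> 10        1.2 constant_total_n 1.481    4.423 0.3348   -1.1295   -1.1295
```

Reading the table: cutting chlorophyll to 40% by shrinking the antenna alone
(`lhc_only`) raises daily canopy uptake ~2% while *saving* 0.47 g N m-2, so
nitrogen-use efficiency jumps ~14%; reinvesting the saved nitrogen
(`constant_total_n`) buys the larger A_c gain at every reduced multiplier.
Raising chlorophyll (1.2×) only costs.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/canophot.R run       --config inst/extdata/default_stand.yaml --seed 1 --out results/
Rscript inst/cli/canophot.R sweep-chl --multipliers 0.4,0.6,0.8,1,1.2 --strategy both --seed 1 --out results/
Rscript inst/cli/canophot.R sweep-arch --latitudes 45,40,31,18 --seed 1 --out results/
Rscript inst/cli/canophot.R trace     --rays 2e4 --seed 1 --out field.csv
```

See `vignettes/canopy-photosynthesis.Rmd` for the full model description,
parameter defaults with units, and known limitations.

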