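# elevdiv

Analysis of species-richness gradients along discrete elevational
transects, built for surveys of the kind used in montane small-mammal
ecology: two slopes of one mountain sampled in fixed elevational bands,
every captured individual identified to species, and band-level
environmental covariates (area, temperature, humidity, NDVI, plant
richness) measured alongside.

The package answers two questions about such a survey:

1. **How much of the richness gradient is geometry?** Random placement of
   bounded species ranges inside a bounded domain produces a mid-elevation
   richness peak with no environmental cause — the *mid-domain effect*
   (MDE). `elevdiv` implements the discrete-domain MDE null model: each
   species' elevational range (a contiguous run of `r` bands) is placed
   with its midpoint uniform over the `m − r + 1` feasible positions while
   the empirical range-size multiset is held fixed. Per band the model
   yields the simulated mean richness, a 95% percentile envelope (5,000
   draws by default), and the closed-form expectation

   E[richness at band *j*] = Σ over species (min(*j*, *m*−*r*+1) −
   max(1, *j*−*r*+1) + 1) / (*m*−*r*+1).

2. **Which drivers explain what the geometry does not?** An
   information-theoretic chain in the MuMIn tradition: Pearson screen
   dropping all but one of each block of collinear covariates
   (|r| > 0.7), all-subsets fitting of the global model
   `richness = slope * (MDE + area + NDVI + …)` under marginality,
   ranking by AICc (= −2 logLik + 2K + 2K(K+1)/(n−K−1)), Akaike weights,
   model averaging over the 95% cumulative-weight confidence set with
   per-term importance (summed weights), VIF checks, and Moran's I on the
   best model's residuals.

Supporting tools: interpolated elevational ranges (presence assumed
between a species' lowest and highest detections), species grouping
(taxon, median range-size split, endemism), polynomial richness trends
compared by AICc, Sorensen similarity, trap success, NDVI from
reflectances — and a fully seeded synthetic trapping-survey generator so
that the entire pipeline can be exercised and validated without field
data.

## Worked example

```r
library(elevdiv)

# A seeded synthetic survey: 6 bands x 2 slopes, 27 + 33 species (23
# shared), ~2,200 trap-nights per band
d <- generate_dataset(ailao_config(seed = 42))
d
#> <synthetic_dataset>
#>   slopes:    west, east
#>   bands:     6 per slope
#>   species:   37 in pool; 60 slope-level ranges
#>   captures:  2173 individuals in 411 records

bands <- seq(1800, 2800, by = 200)
rg   <- build_ranges(d$captures, bands)
rich <- group_richness(rg, d$traits, "total")     # interpolated richness
subset(rich, slope == "west")
#>    slope band elevation richness
#>     west    1      1800        9
#>     west    2      2000       15
#>     west    3      2200       20
#>     west    4      2400       22
#>     west    5      2600       15
#>     west    6      2800       14

# MDE null model for the western assemblage
mde <- simulate_mde(rg$range_size[rg$slope == "west"], m = 6,
                    n_sims = 5000, seed = 1)
mde
#> <mde_prediction> 27 ranges on 6 bands, 5000 simulations
#>  band  mean ci_low ci_high analytic
#>     1 13.20     10      17    13.22
#>     2 16.29     13      20    16.27
#>     3 18.01     15      21    18.02
#>     4 18.02     15      21    18.02
#>     5 16.27     13      20    16.27
#>     6 13.22     10      17    13.22

fit_observed_to_mde(subset(rich, slope == "west")$richness,
                    mde$mean_richness)
#> <mde_fit> R2 = 0.765, P = 0.0225 (n = 6)
```

The observed western gradient peaks mid-slope and the null model alone
explains ~77% of its variance — the hump is largely geometric here, as
expected for richness generated by random range placement.

```r
rep <- run_pipeline(d$captures, d$traits, d$covariates,
                    groups = "total", n_sims = 5000, seed = 1)
rep$groups$total$selection$candidates
#> <candidate_model_set> 35 models
#>  rank     terms K r_squared  aicc delta_aicc weight cum_weight in_conf_set
#>     1       MDE 3     0.744 60.86       0.00  0.665      0.665        TRUE
#>     2  MDE+NDVI 4     0.773 64.09       3.23  0.132      0.797        TRUE
#>     3  MDE+area 4     0.746 65.44       4.58  0.067      0.864        TRUE
#>     4 slope+MDE 4     0.744 65.56       4.70  0.063      0.927        TRUE

rep$groups$total$selection$averaged
#> <averaged_model> 5 models in the confidence set; full averaging
#> relative importance:
#>       MDE      NDVI     slope      area slope:MDE
#>     1.000     0.135     0.117     0.069     0.052

rep$groups$total$selection$moran
#> <moran_result> I = 0.0869 (E = -0.0909), z = 0.601, p = 0.548
```

On this null-generated fixture the selection chain behaves exactly as it
should: the MDE predictor dominates (importance 1.000), no environmental
covariate or slope interaction earns support, and the best model's
residuals show no spatial autocorrelation along the band chains.

A thin command-line wrapper over the same functions ships at
`inst/cli/elevdiv.R` (`simulate`, `richness`, `mde`, `polyfit`, `report`
subcommands).

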