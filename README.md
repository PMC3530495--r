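# clineshift

Maximum-likelihood fitting of geographic clines and coincidence testing for
moving hybrid zones.

## What this is for

When two species meet and interbreed along a transect, a diagnostic trait
scaled 0-1 between the parental forms follows a sigmoid **cline**. This
package estimates where that cline sits and how sharp it is, puts a
likelihood-based interval on the position, and tests whether two clines —
for example the same trait in two historical collection periods, or a trait
cline against a habitat transition — share a common center. It was built
around the textbook case of a moving amphibian hybrid zone: the American
toad (*Anaxyrus americanus*) × Canadian toad (*A. hemiophrys*) contact in
southern Manitoba, whose center oscillated west and then east across the
forest-prairie ecotone over five decades. A synthetic-data generator
reproduces that study's statistical structure so the entire pipeline is
testable without museum specimens.

## The model

Trait value at transect position `x` (km east of a gnomonic projection
center, by default Winnipeg city center at 97.14°W, 49.88°N):

    p(x) = p_min + (p_max − p_min) · ½ [1 + tanh( 2(x − c) / w )]

* `c` — cline center, the steepest point;
* `w` — cline width, the inverse of the maximum slope for a 0-1 cline;
* `p_min`, `p_max` — free tail values;
* site means of `n_i` specimens are Gaussian around `p(x_i)` with standard
  deviation `σ/√n_i`, with a common `σ` estimated as a free parameter.

Fitting uses Metropolis-Hastings chains as a stochastic maximizer followed
by a deterministic polish (tails and `σ` concentrated out in closed form),
so results are bit-reproducible given a seed. Holding `c` fixed on a grid
and re-maximizing everything else gives a log-likelihood profile; the
outermost positions within 2 units of its maximum are the support limits
(≈95% CI). Two clines are compared with the composite-profile
likelihood-ratio statistic

    R = 2 (LLΣ − ΣLL),   R ~ χ²(1 df),

where `LLΣ` is the sum of the two profile maxima (centers free) and `ΣLL`
the maximum of the summed profiles (centers forced equal). Families of
pairwise tests are corrected by sequential Bonferroni (Holm).

## Worked example

```r
library(clineshift)

# simulate a 20-site transect from a cline centered at 40 km, width 10 km
obs <- simulate_cline_observations(seq(0, 95, by = 5), n = 15,
                                   c = 40, w = 10, sigma = 0.05, seed = 1)
fit <- fit_cline(obs, fit_config(seed = 1))
fit
#> Sigmoid cline: center 39.94 km, width 10.24 km, tails [0.000, 1.003], sigma 0.0437
#>   log-likelihood: 61.307

prof <- profile_center(obs, fit_config(seed = 1), fit = fit)
prof
#> Center likelihood profile: 687 points on [-9.5, 104.5] km
#>   c_hat = 39.94 km, Lmax = 61.307
#>   2-unit support: [39.71, 40.16] km

# a second, displaced cline (center 43 km): is it coincident?
obs2 <- simulate_cline_observations(seq(0, 95, by = 5), n = 15,
                                    c = 43, w = 10, sigma = 0.05, seed = 2)
lrt_coincidence(prof, profile_center(obs2, fit_config(seed = 2)))
#> Cline coincidence LRT: R = 65.867 (df = 1), P <0.001
```

The fitted center (39.94 km) sits within a quarter-kilometer support
interval — a 20-site transect with 15 specimens per site pins a 10-km-wide
cline very sharply — and a 3-km displacement between the two simulated
clines is overwhelming evidence against a shared center.

Projecting the Manitoba study's printed cline-center longitudes onto the
transect axis and summarizing the trajectory:

```r
centers <- round(transect_x_km(c(-96.19, -96.37, -96.72, -96.58), 49.88))
centers
#> [1] 68 55 30 40
displacement_summary(centers, c(1961, 1969, 1978, 2007.5))
#> Cline-center displacement (east positive, west negative):
#>  from     to move_km years rate_km_per_yr
#>  1961   1969     -13   8.0      1.6250000
#>  1969   1978     -25   9.0      2.7777778
#>  1978 2007.5      10  29.5      0.3389831
#>   net -28.0 km, total path 48.0 km
```

The hybrid zone moved 38 km west over two intervals (1.6 and 2.8 km/yr),
then 10 km back east: a 28-km net westward displacement over a 48-km total
path.

The full study reproduction — specimens → site observations → eight fitted
clines → three families of coincidence tests → displacement summary — is
one call on the synthetic scenario:

```r
res <- run_pipeline(list(scenario = scenario_config(seed = 1),
                         fit = fit_config(seed = 1)))
res$clines
res$displacement
```

## Package tour

| Area | Functions |
| --- | --- |
| Projection | `projection_center`, `gnomonic_forward`, `gnomonic_inverse`, `transect_x_km`, `transect_x_to_longitude` |
| Morphometrics | `normalize_to_svl50`, `filter_adult_males`, `univariate_discriminant`, `screen_characters`, `scale_trait`, `aggregate_sites` |
| Habitat | `forest_fraction`, `set_average`, `habitat_observations` |
| Cline fitting | `cline_model`, `cline_expectation`, `cline_log_likelihood`, `spline_center_init`, `fit_cline`, `profile_center`, `support_limits` |
| Coincidence | `composite_profile`, `lrt_coincidence`, `sequential_bonferroni`, `compare_all` |
| Synthetic data | `scenario_config`, `simulate_cline_observations`, `generate_specimens`, `generate_reference_specimens`, `generate_site_observations`, `generate_habitat_quadrats` |
| Pipeline & I/O | `run_pipeline`, `displacement_summary`, `read_*`/`write_*` table helpers |

The methods vignette (`vignettes/cline-oscillation-methods.Rmd`) documents
the model, the error structure, the numerical strategy, what the synthetic
generator does and does not emulate, and known limitations.
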