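# golgiring

Quantitative image analysis for cellulose synthase complex (CSC)
trafficking, with built-in synthetic-data generators for validation.

In plant cells, cellulose synthase (CesA) proteins are assembled in the
Golgi apparatus and delivered to the plasma membrane, where active
complexes migrate as they extrude cellulose microfibrils. Confocal imaging
of fluorescent CesA reports on each step of this pathway, but the readouts
are bespoke: whether the Golgi signal forms a peripheral **ring** or a
filled **solid** sphere, how large the fluorescent object is, how many new
CesA foci per membrane area appear per hour after photobleaching, and how
fast foci migrate. `golgiring` implements these measurements as tested,
reusable R functions, and pairs every analysis with a seeded generator
that produces the same kind of data with known ground truth, so each
estimator can be validated by parameter recovery.

The package is written tidyverse-style: tabular inputs and outputs are
tibbles, fitted objects have `tidy()`/`glance()` methods, and result types
have `autoplot()` methods.

## The measurements

**Ring/solid classification and object diameter.** A 1-D intensity
transect through a Golgi body is searched for peaks (topographic
prominence ≥ 20% of the signal range, separation ≥ 200 nm). One peak means
the cargo is an unresolved central spot ("solid"), two peaks a resolved
peripheral ring ("ring"). The profile is then fitted with a
double-Gaussian model

    I(x) = b + A1 exp(−(x−μ1)²/2σ1²) + A2 exp(−(x−μ2)²/2σ2²)

with the separation μ2 − μ1 free for rings and **fixed to the microscope
resolution limit (266 nm)** for solids, since two unresolved rim crossings
cannot be separated optically. The object diameter is the separation plus
the width (FWHM, 2√(2 ln 2)·σ) of each Gaussian:

    D = (μ2 − μ1) + 2√(2 ln 2)·σ1 + 2√(2 ln 2)·σ2

**FRAP delivery rate.** In a post-bleach movie, a focus appearing at frame
t is an insertion event iff (i) no particle was within 500 nm in the two
preceding frames, and (ii) it can be tracked for at least four subsequent
frames. Events are scored in the central 60% × 60% subregion only, and the
rate is events per μm² per hour over the occlusion-corrected exposure.

**Migration speed.** Foci are detected by Laplacian-of-Gaussian filtering,
linked by greedy nearest-neighbour assignment, and each track's speed is
the absolute slope of its principal-axis projection against time
(nm/min) — unbiased under localization noise, unlike mean step length.

**Co-localization and immuno-gold statistics.** Thresholded Manders
coefficients M1/M2 for two-channel images, and the Golgi-periphery
statistic: each gold particle's distance from the centre of the Golgi long
axis, relative to total length (0 = centre, 0.5 = end).

## Worked example

Simulate the mutant-condition Golgi population (820 objects, 54%
generative solid fraction, moderate noise) and recover the fraction:

```r
library(golgiring)

sim <- generate_profile_population(preset("stl_golgi", seed = 1),
                                   imaging_params())
pop <- analyze_population(sim$profiles)
pop
#> <golgi_population: 820 objects>
#>   ring 365 | solid 455 | rejected 0
#>   fraction solid (of classified): 0.555
#>   diameter: mean 1101.7, median 1087.0, sd 419.0 nm (fwhm widths)
```

The recovered solid fraction (55.5%) matches the generative 54% to within
the sampling noise of one seeded population. Fit a single ring profile and
read off its diameter:

```r
ring <- sim$profiles[sim$profiles$source_id == "obj0003", ] # true D = 742 nm
fit <- fit_double_gaussian(ring, mode = "free")
fit
#> <double_gaussian_fit: free mode>
#>   baseline 8.53 | A1 103, A2 83.85
#>   mu1 -359.54, mu2 361.70 nm (separation 721.23 nm)
#>   sigma1 118.57, sigma2 126.98 nm | RSS 1203 | converged: TRUE
object_diameter(fit)
#> # A tibble: 1 × 5
#>   separation_nm w1_nm w2_nm diameter_nm width_definition
#>           <dbl> <dbl> <dbl>       <dbl> <chr>
#> 1          721.  279.  299.       1299. fwhm
```

The fitted separation (721 nm) recovers the generated ring diameter
(742 nm) and the ~280-nm component widths reflect the 266-nm PSF; the
reported object diameter adds the two. Compare two diameter samples with
the F-test-screened t-test:

```r
compare_groups(c(780, 812, 830, 795, 841, 803),
               c(705, 742, 731, 688, 760, 719))
#> # A tibble: 1 × 9
#>   statistic    df  p_value variance_test_p method         mean_a mean_b  n_a  n_b
#> 1      6.14    10 0.000110           0.768 student_pooled   810.   724.    6    6
```

Other entry points follow the same pattern: `generate_frap_movie()` →
`detect_insertion_events()` → `delivery_rate()`;
`generate_track_set()` → `link_trajectories()` → `track_speeds()`;
`generate_coloc_pair()` → `manders()`;
`generate_gold_particles()` → `gold_relative_distance()`. A configurable
end-to-end runner is available as `run_pipeline()` (see `load_config()`),
with a shell wrapper in `inst/scripts/golgiring`.

## Documentation

The methods vignette (`vignettes/golgiring-methods.Rmd`) describes the
models, the synthetic-data generators and their defaults, the numerical
choices, and known limitations.
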