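# myoretina

Quantitative analysis chain for studies that relate retinal microstructure
to spatial vision in high myopia. Such studies measure, on the same eyes:

- **cone-mosaic morphometry** from adaptive-optics (AO) fundus images —
  cone density (cones/mm²), center-to-center spacing (µm), and Voronoi
  regularity (% of cones with 5–7 neighbors) in 100 × 100 µm ROIs at 0.6
  and 1.2 mm eccentricity;
- **choroidal vascularity** from OCT B-scans — choroidal thickness (CT) and
  the choroidal vascularity index CVI = LA/TCA, where luminal (LA) and
  stromal (SA) areas are separated by Niblack's local threshold
  *T = µ_w + k·σ_w* on the boundary-flattened scan;
- **contrast sensitivity functions** — per-frequency contrast thresholds
  estimated with the Bayesian adaptive Psi method (45 trials at each of
  1.5, 3, 6, 12, 18, 24 cpd; threshold = the 80.3%-correct point of a
  Weibull psychometric function with γ = 0.5, λ = 0.02), summarized as the
  area under the log CSF (AULCSF) and the cut-off spatial frequency;
- **cohort statistics** — one-way ANOVA with pairwise t-tests, χ² on sex,
  Pearson correlations, and a univariate → backward-eliminated
  multivariate OLS screen, plus repeatability statistics (ICC(2,1) and the
  coefficient of repeatability 1.96·SD of paired differences).

Lateral dimensions are corrected for ocular magnification with Bennett's
axial-length method, *q* = 0.01306 (AL − 1.82).

Clinical images and subjects cannot be redistributed, so the package
includes synthetic generators for every input — quasi-hexagonal cone
mosaics, two-compartment choroid phantoms with known lumen fraction,
simulated 2AFC observers with truncated log-parabola CSFs, and an 81-eye
cohort with the study's 20/26/35 group structure — making the whole chain
testable offline. The package is aimed at vision scientists and imaging
methodologists who want a reproducible, inspectable reference
implementation of this analysis chain.

## Worked example

```r
library(myoretina)

# simulate an observer and estimate its CSF with the Psi method
obs <- gen_observer(observer_spec(peak_gain = 60, peak_frequency = 2.5, seed = 3))
res <- run_session(obs, n_trials = 45, seed = 3)
print(res)
#> CSF result
#>  frequency_cpd threshold log10_sensitivity
#>            1.5   0.01738              1.76
#>            3.0   0.01905              1.72
#>            6.0   0.02512              1.60
#>           12.0   0.09550              1.02
#>           18.0   0.26300              0.58
#>           24.0   0.57540              0.24
#> AULCSF = 1.6099, cut-off SF = 1.4684 log10 cpd
aulcsf(obs$log_sens_true, obs$frequencies)   # truth: 1.584

# choroid phantom -> flatten -> Niblack -> subfield metrics
ph  <- gen_choroid_phantom(choroid_phantom_spec(lumen_fraction = 0.65, seed = 3))
lin <- linearize(ph$scan, ph$boundaries)
lumen <- niblack_binarize(lin$scan, choroid_mask(lin$scan, lin$boundaries))
choroid_metrics(lin$scan, lin$boundaries, lumen, subfield("inner"))
#> Choroid (inner): CT 300.0 um, TCA 0.3000 mm^2, LA 0.1968 mm^2, CVI 0.656

# cone mosaic: render, detect, measure
sim <- gen_mosaic(mosaic_spec(density = 18000, seed = 3))
det <- detect_cones(sim$image,
                    params = detect_params(expected_spacing = sim$lattice_constant))
mosaic_metrics(det)
#> Cone metrics: 178 cones, density 17800 /mm^2, spacing 8.63 um, regularity 98.5%
```

The session's AULCSF (1.61) sits within estimation error of the observer's
true value (1.58); the phantom's CVI (0.656) reflects the inner subfield's
realized lumen fraction around the 0.65 target; and the detected density
(17,800/mm²) is within 1.2% of the 18,000/mm² generator target.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the study's
stages in order and write tidy tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # synthetic 81-eye cohort        -> cohort.csv
Rscript analysis/02_cones.R      # AO imaging + cone morphometry  -> cone_metrics.csv
Rscript analysis/03_choroid.R    # phantom CT/LA/SA/TCA/CVI       -> choroid_metrics.csv
Rscript analysis/04_csf.R        # Psi sessions, AULCSF, cut-off  -> csf_results.csv
Rscript analysis/05_stats.R      # tables 1-3 analogues           -> table1.csv, ...
```

`run_pipeline()` performs the same stages programmatically with a JSON run
manifest (seed, config hash, package version); reruns with the same seed
are byte-identical.

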