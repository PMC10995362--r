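test_that("mosaic generator hits its target density", {
  sim <- gen_mosaic(mosaic_spec(density = 20000, jitter_sd = 0, dropout = 0,
                                field_um = 1000, seed = 1), render = FALSE)
  realized <- nrow(sim$positions) / 1  # 1 mm^2 field
  expect_lt(abs(realized / 20000 - 1), 0.01)
  expect_equal(sim$lattice_constant, sqrt(2 / (sqrt(3) * 0.02)))
  # Bernoulli thinning: dropout 0.5 halves the density
  thin <- gen_mosaic(mosaic_spec(density = 20000, jitter_sd = 0, dropout = 0.5,
                                 field_um = 1000, seed = 2), render = FALSE)
  expect_lt(abs(nrow(thin$positions) / 10000 - 1), 0.03)
})

test_that("an unjittered mosaic is perfectly regular", {
  sim <- gen_mosaic(mosaic_spec(density = 18000, jitter_sd = 0, dropout = 0,
                                field_um = 250, seed = 3), render = FALSE)
  expect_equal(mosaic_metrics(sim$mosaic)$regularity, 100)
})

test_that("phantom generator honors its lumen-fraction stopping rule", {
  ph <- gen_choroid_phantom(choroid_phantom_spec(lumen_fraction = 0.65, seed = 2))
  expect_gte(ph$lumen_fraction, 0.64)
  expect_lte(ph$lumen_fraction, 0.66)
  expect_equal(ph$lumen_fraction,
               sum(ph$labels == 1L) / sum(ph$labels != 0L))
  # no vessels at all
  ph0 <- gen_choroid_phantom(choroid_phantom_spec(lumen_fraction = 0, seed = 1))
  expect_identical(ph0$lumen_fraction, 0)
  # flat boundaries: CT recovered up to axial quantization
  phf <- gen_choroid_phantom(choroid_phantom_spec(boundary_amplitude = 0,
                                                  ct = 300, seed = 1))
  lin <- linearize(phf$scan, phf$boundaries)
  q <- choroid_metrics(lin$scan, lin$boundaries,
                       matrix(FALSE, nrow(phf$scan$pixels), ncol(phf$scan$pixels)),
                       subfield("inner"))
  expect_lt(abs(q$CT - 300), phf$spec$axial_scale)
})

test_that("observer CSF evaluates the truncated log-parabola exactly", {
  # vertex: S(f0) = G
  expect_equal(log_parabola_csf(3, 100, 3, 3, 10), 2)
  # hand calculation at 24 cpd for G = 100, f0 = 3, w = 3
  hand <- 2 - 4 * log10(2) * ((log10(24) - log10(3)) / 3)^2
  expect_equal(log_parabola_csf(24, 100, 3, 3, 10), hand, tolerance = 1e-12)
  # low-frequency truncation floors the parabola below f0
  expect_equal(log_parabola_csf(0.1, 100, 3, 0.5, 0.3), 2 - 0.3)
  # a nearly-flat parabola integrates to the flat closed form
  obs <- gen_observer(observer_spec(peak_gain = 10, bandwidth = 1e3,
                                    truncation = 0))
  expect_equal(aulcsf(obs$log_sens_true, obs$frequencies), 1 * log10(16),
               tolerance = 1e-4)
  expect_true(all(obs$thresholds > 0 & obs$thresholds <= 1))
  expect_error(observer_spec(peak_gain = 0.5), "peak_gain")
})

test_that("default cohort reproduces the 81-eye group structure and rule", {
  coh <- gen_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(coh), 81)
  expect_equal(as.integer(table(coh$group)), c(20, 26, 35))
  shm <- coh$se <= -6.00 | coh$al >= 26.5
  expect_identical(unname(shm), unname(coh$group == "SHM"))
  # sex counts fixed by design
  expect_equal(as.integer(table(coh$sex, coh$group)["F", ]), c(11, 10, 11))
  # biometry stays inside the printed ranges
  expect_true(all(coh$se[coh$group == "EM"] >= -0.75 &
                    coh$se[coh$group == "EM"] <= 0.75))
  expect_true(all(coh$al[coh$group == "SHM"] >= 25.03 &
                    coh$al[coh$group == "SHM"] <= 29.23))
  # luminal/stromal identities hold row-wise
  expect_equal(coh$la_inner + coh$sa_inner, coh$tca_inner, tolerance = 1e-12)
  expect_equal(coh$la_inner / coh$tca_inner, coh$cvi_inner, tolerance = 1e-12)
})

test_that("zero couplings decorrelate outcomes from axial length", {
  cp <- default_couplings()
  cp$slope <- 0
  big <- gen_cohort(cohort_spec(sizes = c(EM = 150, "LM/MM" = 150, SHM = 200),
                                couplings = cp, seed = 13))
  for (v in c("cone_density_inner", "aulcsf", "ct_inner"))
    expect_lt(abs(correlate(big, "al", v)$r), 0.1)
})

test_that("linear-Gaussian coupling reproduces its analytic correlation", {
  cp <- default_couplings()
  k <- cp$outcome == "cone_density_inner"
  big <- gen_cohort(cohort_spec(sizes = c(EM = 200, "LM/MM" = 200, SHM = 250),
                                couplings = cp, seed = 17))
  sd_al <- sd(big$al)
  rho <- cp$slope[k] * sd_al /
    sqrt((cp$slope[k] * sd_al)^2 + cp$sd[k]^2)
  expect_lt(abs(correlate(big, "al", "cone_density_inner")$r - rho), 0.1)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_mosaic(mosaic_spec(seed = 9))
  b <- gen_mosaic(mosaic_spec(seed = 9))
  expect_identical(a$positions, b$positions)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(gen_choroid_phantom(choroid_phantom_spec(seed = 9))$scan$pixels,
                   gen_choroid_phantom(choroid_phantom_spec(seed = 9))$scan$pixels)
  expect_identical(gen_cohort(cohort_spec(seed = 9)),
                   gen_cohort(cohort_spec(seed = 9)))
})
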