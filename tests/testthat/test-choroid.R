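flat_scan <- function(vals, lateral = 10, axial = 10) {
  bscan(vals, lateral_scale = lateral, axial_scale = axial)
}

test_that("linearize flattens the RPE-Bruch boundary", {
  px <- matrix(as.numeric(seq_len(40 * 30)), 40, 30)
  # already-flat integer boundary: nothing moves
  b0 <- boundary_set(list(rpe_bruch = rep(20, 30), choroid_sclera = rep(35, 30)))
  lin0 <- linearize(flat_scan(px), b0)
  expect_identical(lin0$scan$pixels, px)
  expect_identical(lin0$boundaries$rpe_bruch, rep(20, 30))
  # straight line of slope 1 px/column: integer shifts, variance 0 after
  b1 <- boundary_set(list(rpe_bruch = 5 + 0:29, choroid_sclera = 10 + 0:29))
  lin1 <- linearize(flat_scan(px), b1)
  expect_equal(stats::var(lin1$boundaries$rpe_bruch), 0)
  expect_equal(lin1$boundaries$choroid_sclera - lin1$boundaries$rpe_bruch,
               rep(5, 30))
  # smooth non-integer boundary: residual below half a pixel
  b2 <- boundary_set(list(rpe_bruch = 15 + 4 * sin(2 * pi * (1:30) / 30),
                          choroid_sclera = 30 + 4 * sin(2 * pi * (1:30) / 30)))
  lin2 <- linearize(flat_scan(px), b2)
  expect_lt(stats::sd(lin2$boundaries$rpe_bruch), 0.5)
  expect_error(linearize(flat_scan(px), boundary_set(list(choroid_sclera = rep(3, 30)))),
               "rpe_bruch")
})

test_that("Niblack threshold separates dark objects and ignores constants", {
  # constant region: local sd 0, threshold = mean, nothing strictly below
  sc <- flat_scan(matrix(100, 60, 60))
  lum <- niblack_binarize(sc, matrix(TRUE, 60, 60), niblack_params(window = 31))
  expect_false(any(lum))
  # two-level blocks: dark side of the local mean goes to lumen
  ck <- matrix(220, 60, 60); ck[, 21:40] <- 20
  lum2 <- niblack_binarize(flat_scan(ck), matrix(TRUE, 60, 60),
                           niblack_params(window = 51, k = -0.2))
  expect_true(all(lum2[, 25:36]))
  expect_false(any(lum2[, c(1:16, 45:60)]))
  expect_error(niblack_binarize(sc, matrix(TRUE, 60, 60),
                                niblack_params(window = 61)), "larger")
  expect_error(niblack_params(window = 10), "odd")
})

test_that("CVI is invariant under affine intensity rescaling", {
  ph <- gen_choroid_phantom(choroid_phantom_spec(seed = 6))
  cmask <- choroid_mask(ph$scan, ph$boundaries)
  l1 <- niblack_binarize(ph$scan, cmask)
  sc2 <- ph$scan
  sc2$pixels <- 3.7 * sc2$pixels + 50
  l2 <- niblack_binarize(sc2, cmask)
  expect_identical(l1, l2)
})

test_that("phantom lumen fraction is recovered by the Niblack pipeline", {
  ph <- gen_choroid_phantom(choroid_phantom_spec(lumen_fraction = 0.65, seed = 1))
  expect_gte(ph$lumen_fraction, 0.64)
  expect_lte(ph$lumen_fraction, 0.66)
  lin <- linearize(ph$scan, ph$boundaries)
  cmask <- choroid_mask(lin$scan, lin$boundaries) & !is.na(lin$scan$pixels)
  lum <- niblack_binarize(lin$scan, cmask)
  cvi <- sum(lum & cmask) / sum(cmask)
  expect_lt(abs(cvi - ph$lumen_fraction), 0.05)
})

test_that("recovery error shrinks as phantom contrast grows", {
  err <- vapply(c(150, 120, 60), function(lm) {
    ph <- gen_choroid_phantom(choroid_phantom_spec(lumen_mean = lm, seed = 3))
    cmask <- choroid_mask(ph$scan, ph$boundaries)
    lum <- niblack_binarize(ph$scan, cmask)
    abs(sum(lum & cmask) / sum(cmask) - ph$lumen_fraction)
  }, 0)
  expect_true(all(diff(err) <= 0))
})

test_that("choroid area and thickness arithmetic is exact", {
  # 100 columns x 10 choroid rows = 1000 px of 10 x 10 um
  px <- matrix(0, 20, 100)
  b <- boundary_set(list(rpe_bruch = rep(0, 100), choroid_sclera = rep(10, 100)))
  lumen <- matrix(FALSE, 20, 100)
  lumen[1:10, 1:65] <- TRUE                       # 650 lumen pixels
  sc <- flat_scan(px)
  q <- choroid_metrics(sc, b, lumen, subfield("full", c(0, 0.6)))
  expect_equal(q$TCA, 0.1)
  expect_equal(q$LA, 0.065)
  expect_equal(q$CVI, 0.65)
  expect_equal(q$CT, 100)
  expect_identical(q$n_lumen_pixels + q$n_stroma_pixels, q$n_pixels)
  expect_equal(q$LA + q$SA, q$TCA)
  # empty lumen: CVI 0 and SA = TCA
  q0 <- choroid_metrics(sc, b, matrix(FALSE, 20, 100), subfield("full", c(0, 0.6)))
  expect_identical(q0$CVI, 0)
  expect_identical(q0$SA, q0$TCA)
  # constant separation 30 px at 10 um/px
  px2 <- matrix(0, 40, 100)
  b2 <- boundary_set(list(rpe_bruch = rep(5, 100), choroid_sclera = rep(35, 100)))
  q2 <- choroid_metrics(flat_scan(px2), b2, matrix(FALSE, 40, 100),
                        subfield("full", c(0, 0.6)))
  expect_equal(q2$CT, 300)
})

test_that("sublayer thicknesses equal the per-column oracle", {
  W <- 100
  sc <- bscan(matrix(0, 80, W), lateral_scale = 10, axial_scale = 4)
  mk <- function(is_os_extra) boundary_set(list(
    inl_opl = rep(10, W), opl_onl = rep(17, W), elm = rep(25, W),
    is_os = rep(30, W), os_iz = rep(30, W) + is_os_extra,
    rpe_bruch = rep(45, W), choroid_sclera = rep(100, W)))
  th <- sublayer_thickness(sc, mk(rep(5, W)), subfield("full", c(0, 0.6)))
  expect_equal(unname(th["IS"]), 5 * 4)          # parallel, 5 px at 4 um
  expect_equal(unname(th["OPL"]), 7 * 4)
  # degenerate zero-thickness layer
  th0 <- sublayer_thickness(sc, mk(rep(0, W)), subfield("full", c(0, 0.6)),
                            layers = "OS")
  expect_equal(unname(th0["OS"]), 0)
  # ramp 2 -> 6 px: mean separation 4 px, x 4 um = 16 um
  thr <- sublayer_thickness(sc, mk(seq(2, 6, length.out = W)),
                            subfield("full", c(0, 0.6)), layers = "OS")
  expect_equal(unname(thr["OS"]), 16)
  # brute-force per-column subtraction oracle on an arbitrary smooth pair
  bb <- mk(2 + 3 * sin(2 * pi * (1:W) / W)^2)
  cols <- seq_len(W)
  oracle <- mean(bb$os_iz[cols] - bb$is_os[cols]) * 4
  expect_identical(unname(sublayer_thickness(sc, bb, subfield("full", c(0, 0.6)),
                                             layers = "OS")["OS"]), oracle)
  # crossing boundaries are rejected at construction
  expect_error(mk(rep(-2, W)), "ordered")
})

test_that("repeatability statistics behave at the reference points", {
  x <- c(3.1, 4.5, 2.2, 7.8, 5.0, 6.1)
  ag <- agreement_stats(x, x)
  expect_identical(ag$cor, 0)
  expect_equal(ag$icc, 1)
  # differences with SD exactly 2 -> CoR = 3.92
  d <- c(-2, 0, 2, -2, 0, 2) / stats::sd(c(-2, 0, 2, -2, 0, 2)) * 2
  ag2 <- agreement_stats(x, x + d)
  expect_equal(ag2$cor, 3.92)
  # independent series: ICC near zero
  set.seed(11)
  ag3 <- agreement_stats(rnorm(200), rnorm(200))
  expect_lt(abs(ag3$icc), 0.1)
  expect_error(agreement_stats(1:2, 3:4), "at least 3")
  expect_identical(agreement_stats(rep(1, 5), rep(1, 5))$flag, "zero_variance")
})
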