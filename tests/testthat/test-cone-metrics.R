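hex_mosaic <- function(density, field_um, seed = 1, jitter = 0) {
  gen_mosaic(mosaic_spec(density = density, jitter_sd = jitter, dropout = 0,
                         noise_sd = 0, field_um = field_um, seed = seed),
             render = FALSE)
}

test_that("hexagonal-lattice metrics match the closed forms", {
  s <- 5
  density_cf <- 2 / (sqrt(3) * s^2) * 1e6      # cones/mm^2 for lattice constant s
  sim <- hex_mosaic(density_cf, field_um = 400)
  m <- mosaic_metrics(sim$mosaic)
  expect_lt(abs(m$density / density_cf - 1), 0.01)
  expect_equal(m$regularity, 100)
  expect_equal(m$spacing, s, tolerance = 0.02)
  expect_equal(m$spacing_nn, s, tolerance = 0.02)
})

test_that("density is exactly count over area", {
  sq <- data.frame(x_um = c(45, 55, 45, 55), y_um = c(45, 45, 55, 55))
  m <- mosaic_metrics(cone_mosaic(sq, width_um = 100))
  expect_identical(m$density, 4 / 0.01)
  set.seed(7)
  rnd <- data.frame(x_um = runif(57, 0, 100), y_um = runif(57, 0, 100))
  expect_identical(mosaic_metrics(cone_mosaic(rnd, width_um = 100))$density,
                   57 / 0.01)
})

test_that("spacing and regularity are flagged undefined below 3 cones", {
  m <- mosaic_metrics(cone_mosaic(data.frame(x_um = c(10, 20), y_um = c(10, 20)),
                                  width_um = 100))
  expect_equal(m$density, 200)
  expect_true(is.na(m$spacing))
  expect_true(is.na(m$regularity))
  expect_identical(m$flag, "insufficient_cones")
})

test_that("metrics are invariant under rigid rotation and translation", {
  sim <- hex_mosaic(20000, field_um = 300, seed = 4, jitter = 0.1)
  p <- as.matrix(sim$positions)
  ctr <- c(150, 150)
  keep <- sqrt(rowSums(sweep(p, 2, ctr)^2)) < 130
  p0 <- p[keep, ]
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p1 <- sweep(sweep(p0, 2, ctr) %*% R, 2, ctr + c(8, -6), "+")
  m0 <- mosaic_metrics(cone_mosaic(as.data.frame(stats::setNames(
    list(p0[, 1], p0[, 2]), c("x_um", "y_um"))), width_um = 300))
  m1 <- mosaic_metrics(cone_mosaic(as.data.frame(stats::setNames(
    list(p1[, 1], p1[, 2]), c("x_um", "y_um"))), width_um = 300))
  # interior structure is preserved exactly up to floating noise; cells at
  # the frame border are clipped differently after rotation, so regularity
  # (whose denominator excludes border cells) may move by a cell or two
  expect_equal(m1$spacing, m0$spacing, tolerance = 1e-6)
  expect_equal(m1$spacing_nn, m0$spacing_nn, tolerance = 1e-6)
  expect_lt(abs(m1$regularity - m0$regularity), 0.5)
  expect_identical(m1$density, m0$density)
})

test_that("uniform scaling maps spacing by k and density by 1/k^2", {
  sim <- hex_mosaic(18000, field_um = 200, seed = 9, jitter = 0.08)
  k <- 2.3
  ps <- sim$positions
  scaled <- data.frame(x_um = ps$x_um * k, y_um = ps$y_um * k)
  m0 <- mosaic_metrics(cone_mosaic(ps, width_um = 200))
  m1 <- mosaic_metrics(cone_mosaic(scaled, width_um = 200 * k))
  expect_equal(m1$spacing, k * m0$spacing, tolerance = 1e-9)
  expect_equal(m1$density, m0$density / k^2, tolerance = 1e-12)
  expect_equal(m1$regularity, m0$regularity)
})

test_that("regularity declines with jitter while density is preserved", {
  ms <- lapply(c(0, 0.15, 0.3), function(j)
    mosaic_metrics(hex_mosaic(20000, field_um = 300, seed = 5, jitter = j)$mosaic))
  reg <- vapply(ms, function(m) m$regularity, 0)
  expect_equal(reg[1], 100)
  expect_true(all(diff(reg) <= 0))
  den <- vapply(ms, function(m) m$density, 0)
  expect_true(all(abs(den / den[1] - 1) < 0.02))
})

test_that("average_regions pools ROI metrics arithmetically", {
  mk <- function(density, regularity, label) {
    structure(list(density = density, spacing = 5, spacing_nn = 4.8,
                   regularity = regularity, n_cones = 170L,
                   n_interior = 120L, region_label = label),
              class = "cone_metrics")
  }
  avg <- average_regions(list(mk(16000, 90, "inner"), mk(17000, 95, "inner"),
                              mk(18000, 100, "inner")))
  expect_equal(avg$density, 17000)
  expect_equal(avg$regularity, 95)
  expect_equal(avg$n_cones, 510L)
  one <- mk(16000, 90, "outer")
  expect_equal(average_regions(list(one))$density, one$density)
  expect_equal(average_regions(list(mk(1, 90, "a"), mk(1, 100, "a")))$regularity, 95)
  expect_error(average_regions(list(mk(1, 1, "inner"), mk(1, 1, "outer"))),
               "region_label")
  expect_error(average_regions(list()), "empty")
})
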