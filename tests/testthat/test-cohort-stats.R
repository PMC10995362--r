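test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(21)
  d <- data.frame(y = rnorm(40), group = rep(c("A", "B"), each = 20))
  gc <- compare_groups(d, "y")
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(gc$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(gc$p_overall, tt$p.value, tolerance = 1e-10)
})

test_that("group comparison detects a large shift and flags degeneracy", {
  set.seed(5)
  d <- data.frame(y = c(rnorm(30), rnorm(30), rnorm(30, 2)),
                  group = rep(c("EM", "LM/MM", "SHM"), each = 30))
  gc <- compare_groups(d, "y")
  expect_lt(gc$p_overall, 0.001)
  expect_equal(nrow(gc$pairwise), 3)
  expect_equal(gc$pairwise$label, c("P1", "P2", "P3"))
  dz <- data.frame(y = rep(c(1, 1, 2), each = 5),
                   group = rep(c("a", "b", "c"), each = 5))
  expect_identical(compare_groups(dz, "y")$flag, "zero_within_variance")
  expect_error(compare_groups(data.frame(y = 1:3, group = c("a", "a", "b")), "y"),
               "at least 2")
})

test_that("chi-square sex test matches hand-computed statistics", {
  # perfectly proportional: no association
  prop <- matrix(c(10, 20, 5, 10, 15, 30), nrow = 2)
  r0 <- sex_distribution_test(prop)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  # extreme association: chi-square = 30 by hand
  tab <- matrix(c(10, 0, 0, 10, 0, 10), nrow = 2, byrow = FALSE)
  r1 <- sex_distribution_test(tab)
  expect_equal(r1$statistic, 30, tolerance = 1e-10)
  expect_lt(r1$p, 0.001)
  expect_error(sex_distribution_test(matrix(c(1, 1, 0, 0, 2, 3), nrow = 2)),
               "margin")
})

test_that("Pearson correlation behaves at the reference points", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(correlate(d, "x", "y")$r, 1)
  expect_equal(correlate(data.frame(x = 1:5, y = -(1:5)), "x", "y")$r, -1)
  set.seed(31)
  dn <- data.frame(x = rnorm(500), y = rnorm(500))
  expect_lt(abs(correlate(dn, "x", "y")$r), 0.1)
  expect_error(correlate(data.frame(x = 1:2, y = 1:2), "x", "y"), "at least 3")
})

test_that("standardized betas obey the simple-regression identity", {
  set.seed(41)
  d <- data.frame(x1 = rnorm(100, sd = 3))
  d$y <- 1.7 * d$x1 + rnorm(100)
  rs <- regression_screen(d, "y", "x1")
  b <- rs$univariate
  expect_equal(b$std_beta, b$beta * sd(d$x1) / sd(d$y), tolerance = 1e-10)
  expect_equal(b$std_beta, cor(d$x1, d$y), tolerance = 1e-10)
  # y == x exactly: both coefficients are 1 (lm warns about the perfect fit)
  dd <- data.frame(x1 = rnorm(50)); dd$y <- dd$x1
  bb <- suppressWarnings(regression_screen(dd, "y", "x1"))$final
  expect_equal(bb$beta, 1, tolerance = 1e-10)
  expect_equal(bb$std_beta, 1, tolerance = 1e-10)
})

test_that("screen keeps a planted predictor and drops pure noise", {
  set.seed(51)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d$y <- 2 * d$x1 + rnorm(200)
  rs <- regression_screen(d, "y", c("x1", "x2"))
  expect_identical(rs$final$term, "x1")
  expect_lt(abs(rs$final$beta - 2), 0.2)
  # nothing significant: empty final model, flagged
  dn <- data.frame(x1 = rnorm(60), x2 = rnorm(60), y = rnorm(60))
  rs0 <- regression_screen(dn, "y", c("x1", "x2"))
  expect_equal(nrow(rs0$final), 0)
  expect_true("no_predictor_entered" %in% rs0$flags)
})

test_that("synthetic cohort recovers the generator's association signs", {
  big <- gen_cohort(cohort_spec(sizes = c(EM = 150, "LM/MM" = 150, SHM = 200),
                                seed = 77))
  expect_lt(correlate(big, "al", "cone_density_inner")$r, 0)
  expect_lt(correlate(big, "al", "ct_inner")$r, 0)
  expect_lt(correlate(big, "al", "aulcsf")$r, 0)
  expect_gt(correlate(big, "al", "cone_spacing_inner")$r, 0)
  expect_gt(correlate(big, "cone_density_outer", "aulcsf")$r, 0)
})
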