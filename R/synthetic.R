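#' Specification of a synthetic cone-mosaic image
#'
#' Quasi-hexagonal mosaic: a triangular lattice at the target density, with
#' per-point Gaussian jitter (as a fraction of the lattice constant) and
#' Bernoulli dropout, rendered as a sum of Gaussian spots plus Gaussian
#' noise. Spot amplitude is 1, so `1 / noise_sd` is the peak SNR.
#'
#' @param density Target cone density, cones/mm^2.
#' @param jitter_sd Positional jitter SD as a fraction of the lattice
#'   constant.
#' @param dropout Fraction of cones removed at random.
#' @param spot_sigma Gaussian spot SD, um.
#' @param pixel_scale Rendered pixel pitch, um/pixel.
#' @param noise_sd Additive Gaussian noise SD (spot amplitude is 1).
#' @param field_um Side of the square field, um.
#' @param seed Integer seed; every generator is deterministic under it.
#' @return A list of class `mosaic_spec`.
#' @export
mosaic_spec <- function(density = 17000, jitter_sd = 0.12, dropout = 0.02,
                        spot_sigma = 1.0, pixel_scale = 0.8, noise_sd = 0.1,
                        field_um = 100, seed = 1) {
  stopifnot(density > 0, jitter_sd >= 0, dropout >= 0, dropout < 1,
            spot_sigma > 0, pixel_scale > 0, noise_sd >= 0, field_um > 0)
  structure(as.list(environment()), class = "mosaic_spec")
}

#' Generate a synthetic cone mosaic with ground truth
#'
#' @param spec A [mosaic_spec()].
#' @param render Render the image (set to `FALSE` to generate positions
#'   only, e.g. for point-pattern oracles on large fields).
#' @return List of class `mosaic_sim`: `image` (an [ao_image()], or `NULL`),
#'   `positions` (ground-truth data frame `x_um`, `y_um`), `mosaic` (a
#'   [cone_mosaic()] of the ground truth), `lattice_constant` (um), `spec`.
#' @export
gen_mosaic <- function(spec = mosaic_spec(), render = TRUE) {
  stopifnot(inherits(spec, "mosaic_spec"))
  set.seed(spec$seed)
  s <- sqrt(2 / (sqrt(3) * spec$density * 1e-6))   # lattice constant, um
  row_h <- s * sqrt(3) / 2
  L <- spec$field_um
  jr <- ceiling((L + s) / row_h)
  pts <- do.call(rbind, lapply(0:jr, function(j) {
    xoff <- if (j %% 2 == 1) s / 2 else 0
    x <- seq(-s, L + s, by = s) + xoff + s / 4
    cbind(x, j * row_h + row_h / 4)
  }))
  if (spec$jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$jitter_sd * s),
                        ncol = 2)
  keep <- pts[, 1] >= 0 & pts[, 1] < L & pts[, 2] >= 0 & pts[, 2] < L
  pts <- pts[keep, , drop = FALSE]
  if (spec$dropout > 0)
    pts <- pts[stats::runif(nrow(pts)) >= spec$dropout, , drop = FALSE]
  pos <- data.frame(x_um = pts[, 1], y_um = pts[, 2])
  img <- NULL
  if (render) {
    n_px <- round(L / spec$pixel_scale)
    m <- matrix(0, n_px, n_px)
    sig_px <- spec$spot_sigma / spec$pixel_scale
    r <- ceiling(4 * sig_px)
    for (i in seq_len(nrow(pos))) {
      cx <- pos$x_um[i] / spec$pixel_scale + 0.5
      cy <- pos$y_um[i] / spec$pixel_scale + 0.5
      c0 <- max(1, floor(cx - r)); c1 <- min(n_px, ceiling(cx + r))
      r0 <- max(1, floor(cy - r)); r1 <- min(n_px, ceiling(cy + r))
      if (c0 > c1 || r0 > r1) next
      gx <- exp(-((c0:c1) - cx)^2 / (2 * sig_px^2))
      gy <- exp(-((r0:r1) - cy)^2 / (2 * sig_px^2))
      m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] + outer(gy, gx)
    }
    if (spec$noise_sd > 0)
      m <- m + matrix(stats::rnorm(n_px * n_px, sd = spec$noise_sd),
                      n_px, n_px)
    img <- ao_image(m, spec$pixel_scale)
  }
  structure(list(image = img, positions = pos,
                 mosaic = cone_mosaic(pos, width_um = L, height_um = L),
                 lattice_constant = s, spec = spec),
            class = "mosaic_sim")
}

#' Specification of a two-compartment choroid B-scan phantom
#'
#' A choroid band of constant thickness between two smooth boundaries, with
#' dark elliptical vessel lumens placed by rejection sampling until the
#' labelled lumen fraction is within 0.01 of the target, and a simple
#' layered retina above. Speckle is additive Gaussian noise.
#'
#' @param ct Choroidal thickness, um.
#' @param lumen_fraction Target lumen pixel fraction in \[0, 1\].
#' @param vessel_radius Range of lumen semi-axis radii, um.
#' @param lumen_mean,stroma_mean Mean intensities of the two compartments.
#' @param speckle_sd Additive noise SD.
#' @param lateral_scale,axial_scale Pixel pitches, um/pixel.
#' @param width_mm Scan width, mm.
#' @param retina_offset Depth of the RPE-Bruch complex at the scan center,
#'   um.
#' @param boundary_amplitude Amplitude of the smooth boundary undulation,
#'   um.
#' @param layer_thicknesses Named thicknesses (um) of OPL, HFL_ONL, IS, OS,
#'   IZ_RPE used to place the intraretinal interfaces above the RPE.
#' @param seed Integer seed.
#' @return A list of class `choroid_phantom_spec`.
#' @export
choroid_phantom_spec <- function(ct = 300, lumen_fraction = 0.65,
                                 vessel_radius = c(15, 60),
                                 lumen_mean = 60, stroma_mean = 180,
                                 speckle_sd = 12,
                                 lateral_scale = 10, axial_scale = 5,
                                 width_mm = 4, retina_offset = 250,
                                 boundary_amplitude = 20,
                                 layer_thicknesses = c(OPL = 30, HFL_ONL = 80,
                                                       IS = 30, OS = 35,
                                                       IZ_RPE = 55),
                                 seed = 1) {
  stopifnot(ct > 0, lumen_fraction >= 0, lumen_fraction <= 1,
            length(vessel_radius) == 2, vessel_radius[1] <= vessel_radius[2],
            lateral_scale > 0, axial_scale > 0)
  structure(as.list(environment()), class = "choroid_phantom_spec")
}

#' Generate a choroid B-scan phantom with labels and boundaries
#'
#' @param spec A [choroid_phantom_spec()].
#' @return List of class `choroid_phantom`: `scan` (a [bscan()]),
#'   `boundaries` (a [boundary_set()]), `labels` (integer matrix, 0 outside
#'   the choroid, 1 lumen, 2 stroma), `lumen_fraction` (realized, from the
#'   labels), `spec`.
#' @export
gen_choroid_phantom <- function(spec = choroid_phantom_spec()) {
  stopifnot(inherits(spec, "choroid_phantom_spec"))
  set.seed(spec$seed)
  W <- round(spec$width_mm * 1000 / spec$lateral_scale)
  ct_px <- spec$ct / spec$axial_scale
  H <- round((spec$retina_offset + spec$ct + 100) / spec$axial_scale)
  xs <- seq_len(W)
  amp_px <- spec$boundary_amplitude / spec$axial_scale
  phase <- stats::runif(2, 0, 2 * pi)
  rpe <- spec$retina_offset / spec$axial_scale +
    amp_px * sin(2 * pi * xs / W + phase[1]) +
    0.4 * amp_px * sin(4 * pi * xs / W + phase[2])
  cs <- rpe + ct_px
  lt <- spec$layer_thicknesses / spec$axial_scale
  boundaries <- boundary_set(list(
    inl_opl = rpe - sum(lt),
    opl_onl = rpe - sum(lt[c("HFL_ONL", "IS", "OS", "IZ_RPE")]),
    elm     = rpe - sum(lt[c("IS", "OS", "IZ_RPE")]),
    is_os   = rpe - sum(lt[c("OS", "IZ_RPE")]),
    os_iz   = rpe - lt[["IZ_RPE"]],
    rpe_bruch = rpe,
    choroid_sclera = cs))

  rows <- seq_len(H)
  band <- matrix(FALSE, H, W)
  for (j in xs) band[, j] <- rows > rpe[j] & rows <= cs[j]
  n_band <- sum(band)
  lumen <- matrix(FALSE, H, W)
  target <- spec$lumen_fraction
  if (target > 0 && n_band > 0) {
    frac <- 0
    attempts <- 0
    while (frac < target - 0.01 && attempts < 50000) {
      attempts <- attempts + 1
      r_um <- stats::runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
      rx <- r_um / spec$lateral_scale
      ry <- r_um / spec$axial_scale
      cxj <- stats::runif(1, 1, W)
      cyj <- stats::runif(1, min(rpe), max(cs))
      c0 <- max(1, floor(cxj - rx)); c1 <- min(W, ceiling(cxj + rx))
      r0 <- max(1, floor(cyj - ry)); r1 <- min(H, ceiling(cyj + ry))
      if (c0 > c1 || r0 > r1) next
      sub <- outer(((r0:r1) - cyj)^2 / ry^2, ((c0:c1) - cxj)^2 / rx^2, "+") <= 1
      sub <- sub & band[r0:r1, c0:c1, drop = FALSE]
      gain <- sum(sub & !lumen[r0:r1, c0:c1, drop = FALSE])
      if ((sum(lumen) + gain) / n_band > target + 0.01) next
      lumen[r0:r1, c0:c1] <- lumen[r0:r1, c0:c1] | sub
      frac <- sum(lumen) / n_band
    }
    if (frac < target - 0.01)
      warning("phantom lumen fraction converged to ", round(frac, 3),
              " (target ", target, ")")
  }
  labels <- matrix(0L, H, W)
  labels[band] <- 2L
  labels[lumen] <- 1L

  img <- matrix(150, H, W)                      # sclera / background
  retina <- matrix(FALSE, H, W)
  for (j in xs) retina[, j] <- rows > boundaries$inl_opl[j] & rows <= rpe[j]
  vitreous <- matrix(FALSE, H, W)
  for (j in xs) vitreous[, j] <- rows <= boundaries$inl_opl[j]
  img[vitreous] <- 30
  img[retina] <- 130
  img[band] <- spec$stroma_mean
  img[lumen] <- spec$lumen_mean
  if (spec$speckle_sd > 0)
    img <- img + matrix(stats::rnorm(H * W, sd = spec$speckle_sd), H, W)

  structure(list(scan = bscan(img, spec$lateral_scale, spec$axial_scale),
                 boundaries = boundaries, labels = labels,
                 lumen_fraction = if (n_band > 0) sum(lumen) / n_band else 0,
                 spec = spec),
            class = "choroid_phantom")
}

#' Truncated log-parabola contrast sensitivity function
#'
#' `log10 S(f) = log10 G - 4 log10(2) * ((log10 f - log10 f0) / w)^2`,
#' floored at `log10 G - delta` for `f < f0` (low-frequency truncation).
#'
#' @param f Spatial frequency, cpd.
#' @param peak_gain Peak sensitivity G (> 1).
#' @param peak_frequency Peak frequency f0, cpd.
#' @param bandwidth Width parameter w (octave-like).
#' @param truncation Low-frequency truncation depth delta (log10 units).
#' @return log10 sensitivity at `f`.
#' @export
log_parabola_csf <- function(f, peak_gain, peak_frequency, bandwidth,
                             truncation) {
  stopifnot(peak_gain > 1, peak_frequency > 0, bandwidth > 0, truncation >= 0)
  lg <- log10(peak_gain)
  ls <- lg - 4 * log10(2) * ((log10(f) - log10(peak_frequency)) / bandwidth)^2
  ifelse(f < peak_frequency, pmax(ls, lg - truncation), ls)
}

#' Specification of a simulated 2AFC observer
#'
#' Truncated log-parabola CSF plus a Weibull response model. Defaults are
#' chosen so the default observer's AULCSF falls in the range observed in
#' young adults (about 1.5-1.9).
#'
#' @param peak_gain,peak_frequency,bandwidth,truncation CSF shape; see
#'   [log_parabola_csf()].
#' @param slope Weibull slope of the psychometric function.
#' @param lapse,guess Lapse and guess rates.
#' @param frequencies Spatial frequencies at which the observer is defined.
#' @param seed Integer seed (recorded; response draws happen at session
#'   time).
#' @return A list of class `observer_spec`.
#' @export
observer_spec <- function(peak_gain = 60, peak_frequency = 2.5,
                          bandwidth = 0.85, truncation = 0.4,
                          slope = 3.5, lapse = 0.02, guess = 0.5,
                          frequencies = c(1.5, 3, 6, 12, 18, 24), seed = 1) {
  stopifnot(peak_gain > 1, peak_frequency > 0, bandwidth > 0, truncation >= 0,
            slope > 0, lapse >= 0, lapse < 0.5)
  structure(as.list(environment()), class = "observer_spec")
}

#' Instantiate a simulated observer
#'
#' @param spec An [observer_spec()].
#' @return A list of class `csf_observer` with `frequencies`,
#'   `log_sens_true` (true log10 sensitivities), `thresholds` (true
#'   contrast thresholds, `1/S` clipped to (0, 1\]), `slope`, `guess`,
#'   `lapse`, `spec`. Usable directly with [run_session()].
#' @export
gen_observer <- function(spec = observer_spec()) {
  stopifnot(inherits(spec, "observer_spec"))
  ls <- log_parabola_csf(spec$frequencies, spec$peak_gain,
                         spec$peak_frequency, spec$bandwidth, spec$truncation)
  tau <- pmin(10^(-ls), 1)
  structure(list(frequencies = spec$frequencies, log_sens_true = ls,
                 thresholds = tau, slope = spec$slope, guess = spec$guess,
                 lapse = spec$lapse, spec = spec),
            class = "csf_observer")
}

# default AL couplings of the cohort generator; slopes anchored on the
# study's regression table where units are coherent, otherwise on group
# means over the AL span (see the methods vignette)
default_couplings <- function() {
  df <- rbind(
    data.frame(outcome = "cone_density_inner",  intercept = 58294,  slope = -1578,   sd = 1500),
    data.frame(outcome = "cone_density_outer",  intercept = 54969,  slope = -1435,   sd = 1800),
    data.frame(outcome = "cone_spacing_inner",  intercept = 3.20,   slope = 0.0863,  sd = 0.28),
    data.frame(outcome = "cone_spacing_outer",  intercept = 3.13,   slope = 0.0895,  sd = 0.32),
    data.frame(outcome = "cone_regularity",     intercept = 143.7,  slope = -2.14,   sd = 5),
    data.frame(outcome = "ct_inner",            intercept = 600,    slope = -13.845, sd = 20.8),
    data.frame(outcome = "ct_outer",            intercept = 612,    slope = -14.333, sd = 21),
    data.frame(outcome = "cvi_inner",           intercept = 0.954,  slope = -0.012,  sd = 0.03),
    data.frame(outcome = "cvi_outer",           intercept = 0.954,  slope = -0.012,  sd = 0.03),
    data.frame(outcome = "tca_inner",           intercept = 1.236,  slope = -0.035,  sd = 0.05),
    data.frame(outcome = "tca_outer",           intercept = 1.236,  slope = -0.035,  sd = 0.05),
    data.frame(outcome = "aulcsf",              intercept = 3.33,   slope = -0.066,  sd = 0.386),
    data.frame(outcome = "cutoff_sf",           intercept = 2.16,   slope = -0.032,  sd = 0.17),
    data.frame(outcome = "is_inner",            intercept = 39.0,   slope = -0.357,  sd = 1.22),
    data.frame(outcome = "is_outer",            intercept = 39.1,   slope = -0.359,  sd = 1.20),
    data.frame(outcome = "os_inner",            intercept = 34.2,   slope = 0.032,   sd = 0.80),
    data.frame(outcome = "os_outer",            intercept = 33.1,   slope = 0.075,   sd = 0.90),
    data.frame(outcome = "izrpe_inner",         intercept = 56.8,   slope = -0.073,  sd = 0.85),
    data.frame(outcome = "izrpe_outer",         intercept = 57.9,   slope = -0.113,  sd = 0.90),
    data.frame(outcome = "opl_inner",           intercept = 31.3,   slope = -0.05,   sd = 2.0),
    data.frame(outcome = "opl_outer",           intercept = 31.3,   slope = -0.05,   sd = 2.0),
    data.frame(outcome = "hfl_onl_inner",       intercept = 95,     slope = 0,       sd = 6.0),
    data.frame(outcome = "hfl_onl_outer",       intercept = 95,     slope = 0,       sd = 6.0),
    data.frame(outcome = "flow_superficial_inner", intercept = 32.8, slope = 0.60,   sd = 2.40),
    data.frame(outcome = "flow_superficial_outer", intercept = 63.2, slope = -0.60,  sd = 6.60),
    data.frame(outcome = "flow_deep_inner",     intercept = 37.8,   slope = 0.56,    sd = 2.65),
    data.frame(outcome = "flow_deep_outer",     intercept = 73.8,   slope = -0.86,   sd = 5.12),
    data.frame(outcome = "faz_area",            intercept = 1.413,  slope = -0.044,  sd = 0.166))
  df
}

#' Specification of a synthetic study cohort
#'
#' Per-group biometry drawn from truncated normals matching the study's
#' baseline table (group sizes 20/26/35; SE, AL, age, IOP means, SDs and
#' printed ranges; fixed sex counts), with downstream outcomes generated as
#' linear functions of AL plus Gaussian noise. Coupling signs match the
#' study's associations (negative for cone density, CT, CVI, TCA, AULCSF;
#' positive for cone spacing). Group labels are re-derived from the
#' enrollment rule (SHM iff SE <= -6.00 D or AL >= 26.5 mm) and mismatching
#' draws are resampled.
#'
#' @param sizes Named group sizes, default `c(EM = 20, "LM/MM" = 26,
#'   SHM = 35)`.
#' @param couplings Data frame with columns `outcome`, `intercept`, `slope`,
#'   `sd`; see `myoretina:::default_couplings()` for the defaults.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(sizes = c(EM = 20, "LM/MM" = 26, SHM = 35),
                        couplings = default_couplings(), seed = 1) {
  stopifnot(all(sizes >= 0), all(couplings$sd >= 0))
  structure(list(sizes = sizes, couplings = couplings, seed = seed),
            class = "cohort_spec")
}

# per-group biometry parameters from the study's baseline table
.group_params <- data.frame(
  group   = c("EM", "LM/MM", "SHM"),
  se_mean = c(-0.15, -3.65, -8.00), se_sd = c(0.35, 1.60, 1.50),
  se_lo   = c(-0.75, -6.00, -10.50), se_hi = c(0.75, -0.75, -4.25),
  al_mean = c(23.64, 24.76, 26.77), al_sd = c(0.69, 0.78, 1.05),
  al_lo   = c(22.45, 23.31, 25.03), al_hi = c(24.80, 27.03, 29.23),
  age_mean = c(23.35, 23.27, 23.57), age_sd = c(1.66, 1.66, 2.39),
  age_lo  = c(22, 22, 19), age_hi = c(27, 29, 30),
  iop_mean = c(14.44, 15.70, 16.14), iop_sd = c(3.16, 2.78, 2.57),
  iop_lo  = c(9.70, 10.90, 12.10), iop_hi = c(20, 20.50, 21),
  n_female = c(11, 10, 11))

# truncated normal by rejection
rtrunc1 <- function(mean, sd, lo, hi) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal sampling failed")
}

# SHM enrollment rule
is_shm_rule <- function(se, al) se <= -6.00 | al >= 26.5

#' Generate a synthetic study cohort
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per eye: `id`, `group`, `sex`, `age`,
#'   `se`, `al`, `iop`, the AL-coupled outcomes of
#'   `myoretina:::default_couplings()`, and the derived areas `la_inner`,
#'   `la_outer` (`= tca * cvi`), `sa_inner`, `sa_outer` (`= tca - la`). The
#'   generating spec is attached as attribute `"spec"`.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  gp <- .group_params
  rows <- list()
  id <- 0L
  for (gi in seq_len(nrow(gp))) {
    g <- gp[gi, ]
    n <- spec$sizes[[g$group]]
    if (is.null(n) || n == 0) next
    sex <- sample(c(rep("F", g$n_female), rep("M", n - g$n_female)))
    for (i in seq_len(n)) {
      for (try in 1:1000) {
        se <- rtrunc1(g$se_mean, g$se_sd, g$se_lo, g$se_hi)
        al <- rtrunc1(g$al_mean, g$al_sd, g$al_lo, g$al_hi)
        shm <- is_shm_rule(se, al)
        ok <- if (g$group == "SHM") shm else !shm
        if (ok) break
      }
      id <- id + 1L
      rows[[id]] <- data.frame(
        id = sprintf("S%03d", id), group = g$group, sex = sex[i],
        age = rtrunc1(g$age_mean, g$age_sd, g$age_lo, g$age_hi),
        se = se, al = al,
        iop = rtrunc1(g$iop_mean, g$iop_sd, g$iop_lo, g$iop_hi))
    }
  }
  out <- do.call(rbind, rows)
  cp <- spec$couplings
  for (k in seq_len(nrow(cp))) {
    out[[cp$outcome[k]]] <- cp$intercept[k] + cp$slope[k] * out$al +
      stats::rnorm(nrow(out), sd = cp$sd[k])
  }
  if ("cone_regularity" %in% names(out))
    out$cone_regularity <- pmin(pmax(out$cone_regularity, 0), 100)
  if ("faz_area" %in% names(out))
    out$faz_area <- pmax(out$faz_area, 0.01)
  for (sf in c("inner", "outer")) {
    cvi <- out[[paste0("cvi_", sf)]]
    tca <- out[[paste0("tca_", sf)]]
    if (!is.null(cvi) && !is.null(tca)) {
      cvi <- pmin(pmax(cvi, 0), 1)
      tca <- pmax(tca, 0.05)
      out[[paste0("cvi_", sf)]] <- cvi
      out[[paste0("tca_", sf)]] <- tca
      out[[paste0("la_", sf)]] <- tca * cvi
      out[[paste0("sa_", sf)]] <- tca * (1 - cvi)
    }
  }
  out$group <- factor(out$group, levels = gp$group)
  attr(out, "spec") <- spec
  out
}
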