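#' Adaptive-optics image container
#'
#' Wraps a grayscale AO fundus montage with its physical pixel scale (after
#' magnification correction) and the fovea location in pixel coordinates.
#'
#' @param pixels Numeric matrix of intensities (rows = y, cols = x).
#' @param pixel_scale Micrometers per pixel (> 0).
#' @param fovea_xy Fovea position `c(x, y)` in pixels; defaults to the image
#'   center.
#' @return An object of class `ao_image`.
#' @export
ao_image <- function(pixels, pixel_scale, fovea_xy = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_scale > 0)
  if (is.null(fovea_xy)) fovea_xy <- c(ncol(pixels) / 2, nrow(pixels) / 2)
  if (fovea_xy[1] < 1 || fovea_xy[1] > ncol(pixels) ||
      fovea_xy[2] < 1 || fovea_xy[2] > nrow(pixels))
    stop("fovea_xy must lie inside the image")
  structure(list(pixels = pixels, pixel_scale = pixel_scale,
                 fovea_xy = as.numeric(fovea_xy)),
            class = "ao_image")
}

#' Region-of-interest specification on an AO montage
#'
#' Square ROI placed at a given eccentricity from the fovea along one of the
#' four principal meridians. The default geometry follows the study design:
#' 100 x 100 um ROIs at 0.6 mm ("inner") and 1.2 mm ("outer") eccentricity.
#'
#' @param center_eccentricity Eccentricity of the ROI center, mm (>= 0).
#' @param meridian One of `"superior"`, `"temporal"`, `"inferior"`, `"nasal"`.
#' @param side_length ROI side, um (> 0).
#' @param region_label `"inner"` or `"outer"`; derived from the eccentricity
#'   when `NULL` (inner below 0.9 mm).
#' @param offset_um Manual `c(x, y)` offset of the ROI center in um, e.g. to
#'   avoid blood vessels (ROI placement is the caller's responsibility).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_eccentricity, meridian = "temporal",
                     side_length = 100, region_label = NULL,
                     offset_um = c(0, 0)) {
  meridian <- match.arg(meridian, c("superior", "temporal", "inferior", "nasal"))
  stopifnot(center_eccentricity >= 0, side_length > 0)
  if (is.null(region_label))
    region_label <- if (center_eccentricity < 0.9) "inner" else "outer"
  structure(list(center_eccentricity = center_eccentricity, meridian = meridian,
                 side_length = side_length, region_label = region_label,
                 offset_um = offset_um),
            class = "roi_spec")
}

# Pixel bounds (cols x0:x1, rows y0:y1) of an ROI on an image. Image y grows
# downward, so "superior" is -y.
roi_bounds <- function(image, roi) {
  dir <- switch(roi$meridian,
                temporal = c(1, 0), nasal = c(-1, 0),
                superior = c(0, -1), inferior = c(0, 1))
  center_px <- image$fovea_xy +
    (dir * roi$center_eccentricity * 1000 + roi$offset_um) / image$pixel_scale
  half <- roi$side_length / 2 / image$pixel_scale
  x0 <- round(center_px[1] - half); y0 <- round(center_px[2] - half)
  n <- round(roi$side_length / image$pixel_scale)
  x1 <- x0 + n - 1; y1 <- y0 + n - 1
  if (x0 < 1 || y0 < 1 || x1 > ncol(image$pixels) || y1 > nrow(image$pixels))
    stop("ROI extends outside the image")
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

#' Cone detection parameters
#'
#' @param expected_spacing Expected cone center-to-center spacing, um; tunes
#'   the band-pass filter and the minimum-separation constraint.
#' @param min_sep_frac Minimum allowed separation between detections as a
#'   fraction of `expected_spacing`.
#' @param dog_sigma_frac Small/large Gaussian sigmas of the difference-of-
#'   Gaussians band-pass, as fractions of the expected spacing (in um).
#' @param refine_frac Radius of the center-of-mass refinement window as a
#'   fraction of the expected spacing.
#' @param response_floor_frac Detections must exceed this fraction of the ROI
#'   intensity range in band-pass response; suppresses maxima in flat areas.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(expected_spacing = 5, min_sep_frac = 0.5,
                          dog_sigma_frac = c(0.17, 0.5), refine_frac = 0.25,
                          response_floor_frac = 0.02) {
  stopifnot(expected_spacing > 0, min_sep_frac > 0,
            length(dog_sigma_frac) == 2, dog_sigma_frac[1] < dog_sigma_frac[2])
  structure(list(expected_spacing = expected_spacing,
                 min_sep_frac = min_sep_frac, dog_sigma_frac = dog_sigma_frac,
                 refine_frac = refine_frac,
                 response_floor_frac = response_floor_frac),
            class = "detect_params")
}

#' Detect cone photoreceptors in an ROI
#'
#' Band-pass filters the ROI with a difference of Gaussians tuned to the
#' expected cone period, finds local intensity maxima above a response floor,
#' enforces a minimum separation (strongest response wins), and refines each
#' center to sub-pixel precision by center of mass in a small neighborhood.
#'
#' @param image An [ao_image()].
#' @param roi An [roi_spec()], or `NULL` to treat the whole image as one ROI.
#' @param params A [detect_params()] list.
#' @return A [cone_mosaic()] with positions in um in the ROI frame (origin at
#'   the ROI's top-left corner).
#' @export
detect_cones <- function(image, roi = NULL, params = detect_params()) {
  stopifnot(inherits(image, "ao_image"))
  ps <- image$pixel_scale
  if (is.null(roi)) {
    crop <- image$pixels
    side_x <- ncol(crop) * ps; side_y <- nrow(crop) * ps
  } else {
    b <- roi_bounds(image, roi)
    crop <- image$pixels[b$y0:b$y1, b$x0:b$x1, drop = FALSE]
    side_x <- ncol(crop) * ps; side_y <- nrow(crop) * ps
  }
  s_px <- params$expected_spacing / ps
  rng <- diff(range(crop))
  if (rng == 0) {
    warning("flat ROI: no cones detected")
    return(cone_mosaic(data.frame(x_um = numeric(0), y_um = numeric(0)),
                       width_um = side_x, height_um = side_y, roi = roi))
  }
  sig <- pmax(0.5, params$dog_sigma_frac * s_px)
  resp <- gaussian_blur(crop, sig[1]) - gaussian_blur(crop, sig[2])

  mx <- local_maxima(resp)
  cand <- which(mx & resp > params$response_floor_frac * rng, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    warning("no cones detected in ROI")
    return(cone_mosaic(data.frame(x_um = numeric(0), y_um = numeric(0)),
                       width_um = side_x, height_um = side_y, roi = roi))
  }
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  min_sep <- params$min_sep_frac * s_px
  sel <- greedy_min_sep(cand[, 2], cand[, 1], min_sep)
  cand <- cand[sel, , drop = FALSE]

  # sub-pixel refinement: center of mass of the background-subtracted
  # band-pass response in a small window
  rr <- max(1L, as.integer(round(params$refine_frac * s_px)))
  pos <- matrix(NA_real_, nrow(cand), 2)
  for (i in seq_len(nrow(cand))) {
    r0 <- max(1, cand[i, 1] - rr); r1 <- min(nrow(resp), cand[i, 1] + rr)
    c0 <- max(1, cand[i, 2] - rr); c1 <- min(ncol(resp), cand[i, 2] + rr)
    w <- resp[r0:r1, c0:c1, drop = FALSE]
    w <- w - min(w)
    if (sum(w) <= 0) {
      pos[i, ] <- c(cand[i, 2], cand[i, 1])
    } else {
      cols <- matrix(c0:c1, nrow(w), ncol(w), byrow = TRUE)
      rows <- matrix(r0:r1, nrow(w), ncol(w))
      pos[i, ] <- c(sum(w * cols), sum(w * rows)) / sum(w)
    }
  }
  x_um <- pmin(pmax((pos[, 1] - 0.5) * ps, 0), side_x)
  y_um <- pmin(pmax((pos[, 2] - 0.5) * ps, 0), side_y)
  o <- order(y_um, x_um)
  cone_mosaic(data.frame(x_um = x_um[o], y_um = y_um[o]),
              width_um = side_x, height_um = side_y, roi = roi)
}

#' Cone mosaic container
#'
#' Detected (or ground-truth) cone positions in physical units within an ROI
#' frame whose origin is the ROI's top-left corner.
#'
#' @param positions `data.frame` with columns `x_um`, `y_um`.
#' @param width_um,height_um ROI frame dimensions, um.
#' @param roi Optional [roi_spec()] the positions belong to.
#' @param min_separation If > 0, validate that no two cones are closer than
#'   this distance (um).
#' @return An object of class `cone_mosaic`.
#' @export
cone_mosaic <- function(positions, width_um, height_um = width_um, roi = NULL,
                        min_separation = 0) {
  stopifnot(is.data.frame(positions),
            all(c("x_um", "y_um") %in% names(positions)),
            width_um > 0, height_um > 0)
  if (nrow(positions) > 0) {
    eps <- 1e-9
    if (any(positions$x_um < -eps | positions$x_um > width_um + eps |
            positions$y_um < -eps | positions$y_um > height_um + eps))
      stop("cone positions outside the ROI frame")
    if (min_separation > 0 && nrow(positions) > 1) {
      d <- stats::dist(positions[, c("x_um", "y_um")])
      if (min(d) < min_separation)
        stop("cone positions violate the minimum separation of ",
             min_separation, " um")
    }
  }
  structure(list(positions = positions, width_um = width_um,
                 height_um = height_um, roi = roi),
            class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("Cone mosaic: %d cones in a %.0f x %.0f um frame\n",
              nrow(x$positions), x$width_um, x$height_um))
  invisible(x)
}

#' Density, spacing, and regularity of a cone mosaic
#'
#' Density is the raw count divided by the ROI area (cones/mm^2). Spacing is
#' the mean Euclidean length of retained Delaunay edges ("adjacent cones");
#' edges longer than `edge_prune` times the median edge length are discarded
#' to suppress convex-hull artifacts. Regularity is the percentage of cones
#' with 5-7 Voronoi neighbors among cones whose Voronoi cell is not clipped
#' by the ROI border (border cells would have undercounted neighbors).
#'
#' @param mosaic A [cone_mosaic()].
#' @param edge_prune Delaunay edges longer than this multiple of the median
#'   edge length are excluded from the spacing average.
#' @return An object of class `cone_metrics` with fields `density`
#'   (cones/mm^2), `spacing` (um, Delaunay-edge mean), `spacing_nn` (um,
#'   mean nearest-neighbor distance), `regularity` (percent), `n_cones`,
#'   `n_interior` (cones with unclipped cells), and `region_label`.
#' @export
mosaic_metrics <- function(mosaic, edge_prune = 3) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  p <- mosaic$positions
  n <- nrow(p)
  area_mm2 <- mosaic$width_um * mosaic$height_um / 1e6
  region <- if (!is.null(mosaic$roi)) mosaic$roi$region_label else NA_character_
  out <- list(density = n / area_mm2, spacing = NA_real_, spacing_nn = NA_real_,
              regularity = NA_real_, n_cones = n, n_interior = NA_integer_,
              region_label = region)
  if (n < 3) {
    out$flag <- "insufficient_cones"
    return(structure(out, class = "cone_metrics"))
  }
  dd <- deldir::deldir(p$x_um, p$y_um,
                       rw = c(0, mosaic$width_um, 0, mosaic$height_um),
                       suppressMsge = TRUE)
  seg <- dd$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  retained <- len <= edge_prune * stats::median(len)
  out$spacing <- mean(len[retained])
  # nearest neighbor is always a Delaunay neighbor
  nnd <- tapply(c(len, len), c(seg$ind1, seg$ind2), min)
  out$spacing_nn <- mean(nnd)

  # Voronoi edge list: neighbor count = number of cell sides; a cell whose
  # edges were clipped at the ROI rectangle (bp flags) touches the border
  vs <- dd$dirsgs
  nbr <- tabulate(c(vs$ind1, vs$ind2), nbins = n)
  hit <- vs$bp1 | vs$bp2
  clipped <- rep(FALSE, n)
  clipped[unique(c(vs$ind1[hit], vs$ind2[hit]))] <- TRUE
  interior <- which(!clipped)
  out$n_interior <- length(interior)
  if (length(interior) > 0) {
    out$regularity <- 100 * mean(nbr[interior] >= 5 & nbr[interior] <= 7)
  } else {
    out$flag <- "no_interior_cells"
  }
  structure(out, class = "cone_metrics")
}

#' @export
print.cone_metrics <- function(x, ...) {
  cat(sprintf(
    "Cone metrics: %d cones, density %.0f /mm^2, spacing %.2f um, regularity %.1f%%\n",
    x$n_cones, x$density, x$spacing, x$regularity))
  invisible(x)
}

#' Pool ROI metrics within a region
#'
#' Unweighted arithmetic mean of density, spacing, and regularity over the
#' ROIs of one region (meridians pooled), as in averaging the three ROIs per
#' location.
#'
#' @param metrics_per_roi List of [mosaic_metrics()] results sharing a
#'   `region_label`.
#' @return A `cone_metrics` object of per-region averages (`n_cones` summed).
#' @export
average_regions <- function(metrics_per_roi) {
  if (length(metrics_per_roi) == 0) stop("empty metrics list")
  stopifnot(all(vapply(metrics_per_roi, inherits, TRUE, "cone_metrics")))
  labs <- unique(vapply(metrics_per_roi, function(m) m$region_label, ""))
  if (length(labs) > 1)
    stop("all ROIs must share a region_label; got ", paste(labs, collapse = ", "))
  avg <- function(f) mean(vapply(metrics_per_roi, function(m) m[[f]], 0))
  structure(list(density = avg("density"), spacing = avg("spacing"),
                 spacing_nn = avg("spacing_nn"), regularity = avg("regularity"),
                 n_cones = sum(vapply(metrics_per_roi,
                                      function(m) m$n_cones, 0L)),
                 n_interior = NA_integer_, region_label = labs),
            class = "cone_metrics")
}

# --- small image utilities -------------------------------------------------

# Gaussian smoothing (EBImage, replicated borders)
gaussian_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

# Logical matrix of strict-ish local maxima over the 8-neighborhood.
# Ties on plateaus are broken half-strictly so a flat pair yields one maximum.
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  m >  sh(0, 1)  & m >  sh(1, 0)  & m >  sh(1, 1)  & m >  sh(1, -1) &
  m >= sh(0, -1) & m >= sh(-1, 0) & m >= sh(-1, -1) & m >= sh(-1, 1)
}

# Greedy minimum-separation thinning; input ordered by decreasing response.
greedy_min_sep <- function(x, y, min_sep) {
  n <- length(x)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  m2 <- min_sep^2
  for (i in seq_len(n)) {
    if (length(kx) == 0 || all((kx - x[i])^2 + (ky - y[i])^2 >= m2)) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  which(keep)
}
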