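#' OCT B-scan container
#'
#' @param pixels Numeric intensity matrix (rows = depth, cols = lateral).
#' @param lateral_scale Lateral um/pixel (after magnification correction).
#' @param axial_scale Axial um/pixel (optically calibrated; not AL-corrected).
#' @param fovea_column Column index of the fovea.
#' @param orientation `"horizontal"` or `"vertical"` scan line.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, lateral_scale, axial_scale,
                  fovea_column = round(ncol(pixels) / 2),
                  orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(pixels), lateral_scale > 0, axial_scale > 0)
  if (fovea_column < 1 || fovea_column > ncol(pixels))
    stop("fovea_column outside scan width")
  structure(list(pixels = pixels, lateral_scale = lateral_scale,
                 axial_scale = axial_scale, fovea_column = fovea_column,
                 orientation = orientation),
            class = "bscan")
}

# Interfaces delimiting the outer-retinal sublayers, ordered by depth.
# Layer thicknesses are differences between consecutive named interfaces.
.layer_map <- list(
  OPL      = c("inl_opl", "opl_onl"),
  HFL_ONL  = c("opl_onl", "elm"),
  IS       = c("elm", "is_os"),
  OS       = c("is_os", "os_iz"),
  IZ_RPE   = c("os_iz", "rpe_bruch")
)

#' Boundary annotation set for a B-scan
#'
#' Named polylines, one depth value (pixel row, can be fractional) per
#' column. Required for choroid analysis: `rpe_bruch` (RPE-Bruch's membrane
#' complex) and `choroid_sclera` (choroid-sclera interface). Optional
#' intraretinal interfaces, ordered by increasing depth:
#' `inl_opl`, `opl_onl`, `elm`, `is_os`, `os_iz` (above `rpe_bruch`).
#'
#' @param boundaries Named list of numeric vectors of equal length (one
#'   value per analyzed column).
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(boundaries) {
  stopifnot(is.list(boundaries), !is.null(names(boundaries)))
  lens <- lengths(boundaries)
  if (length(unique(lens)) != 1)
    stop("all boundary polylines must span the same columns")
  if (all(c("rpe_bruch", "choroid_sclera") %in% names(boundaries)) &&
      any(boundaries$choroid_sclera < boundaries$rpe_bruch))
    stop("choroid_sclera must lie at or below rpe_bruch in every column")
  ord <- intersect(c("inl_opl", "opl_onl", "elm", "is_os", "os_iz", "rpe_bruch"),
                   names(boundaries))
  if (length(ord) > 1) {
    # equal depths (zero-thickness layer) are tolerated; crossings are not
    for (i in seq_len(length(ord) - 1)) {
      if (any(boundaries[[ord[i + 1]]] < boundaries[[ord[i]]]))
        stop("intraretinal boundaries must be ordered by depth (",
             ord[i], " vs ", ord[i + 1], ")")
    }
  }
  structure(boundaries, class = "boundary_set")
}

#' Flatten a B-scan to the RPE-Bruch boundary
#'
#' Shifts each column vertically (by an integer number of pixels) so the
#' RPE-Bruch complex lies on a common row; all boundaries are shifted
#' consistently. Rows shifted in from outside the frame are filled with `NA`
#' and excluded from all later masks.
#'
#' @param scan A [bscan()].
#' @param boundaries A [boundary_set()] containing `rpe_bruch`.
#' @param target_row Common row for the flattened RPE-Bruch boundary;
#'   defaults to the rounded median of the input boundary.
#' @return List with elements `scan` (flattened [bscan()]) and `boundaries`
#'   (shifted [boundary_set()]).
#' @export
linearize <- function(scan, boundaries, target_row = NULL) {
  stopifnot(inherits(scan, "bscan"))
  if (!inherits(boundaries, "boundary_set")) boundaries <- boundary_set(boundaries)
  rpe <- boundaries$rpe_bruch
  if (is.null(rpe)) stop("boundary set lacks 'rpe_bruch'")
  if (length(rpe) != ncol(scan$pixels))
    stop("rpe_bruch must be defined over all scan columns")
  if (is.null(target_row)) target_row <- round(stats::median(rpe))
  shift <- round(target_row - rpe)          # positive: move column down
  px <- scan$pixels
  out <- matrix(NA_real_, nrow(px), ncol(px))
  for (j in seq_len(ncol(px))) {
    s <- shift[j]
    src <- seq_len(nrow(px))
    dst <- src + s
    ok <- dst >= 1 & dst <= nrow(px)
    out[dst[ok], j] <- px[src[ok], j]
  }
  shifted <- lapply(unclass(boundaries), function(b) b + shift)
  list(scan = bscan(out, scan$lateral_scale, scan$axial_scale,
                    scan$fovea_column, scan$orientation),
       boundaries = boundary_set(shifted))
}

#' Niblack binarization parameters
#'
#' @param window Local window side in pixels (odd, >= 3).
#' @param k Niblack weight; the local threshold is
#'   `mean + k * sd`. Negative `k` pushes the threshold below the local
#'   mean, the classic choice for dark-object segmentation.
#' @return A list of class `niblack_params`.
#' @export
niblack_params <- function(window = 51, k = -0.2) {
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  structure(list(window = as.integer(window), k = k), class = "niblack_params")
}

#' Niblack local thresholding of the choroid
#'
#' Classifies choroid pixels into lumen (hyporeflective, below the local
#' threshold) and stroma. The per-pixel threshold is
#' `T = local mean + k * local sd` over a square window; lumen pixels are
#' those with intensity strictly below `T`, restricted to the mask. The rule
#' is invariant to affine intensity rescaling with positive gain.
#'
#' @param scan A [bscan()] (typically the linearized scan).
#' @param mask Logical matrix marking the choroid region (e.g. from
#'   [choroid_mask()]).
#' @param params A [niblack_params()] list.
#' @return Logical lumen mask (same dimensions as the scan).
#' @export
niblack_binarize <- function(scan, mask, params = niblack_params()) {
  stopifnot(inherits(scan, "bscan"), is.logical(mask),
            all(dim(mask) == dim(scan$pixels)))
  if (!any(mask)) stop("empty choroid mask")
  px <- scan$pixels
  w <- params$window
  if (w > nrow(px) || w > ncol(px))
    stop("Niblack window larger than the image")
  valid <- !is.na(px)
  x <- ifelse(valid, px, 0)
  n <- box_sum(valid * 1, w)
  s1 <- box_sum(x, w)
  s2 <- box_sum(x^2, w)
  mu <- s1 / pmax(n, 1)
  varv <- pmax(s2 / pmax(n, 1) - mu^2, 0)
  thr <- mu + params$k * sqrt(varv)
  # tiny tolerance so a numerically-exact constant region yields no lumen
  lumen <- valid & mask & (px < thr - 1e-8)
  lumen
}

#' Choroid region mask from boundaries
#'
#' Marks pixels strictly below the RPE-Bruch boundary down to and including
#' the choroid-sclera interface, column by column.
#'
#' @param scan A [bscan()].
#' @param boundaries A [boundary_set()] with `rpe_bruch` and `choroid_sclera`.
#' @param columns Optional integer vector restricting the mask to columns.
#' @return Logical matrix.
#' @export
choroid_mask <- function(scan, boundaries, columns = NULL) {
  px <- scan$pixels
  if (is.null(columns)) columns <- seq_len(ncol(px))
  m <- matrix(FALSE, nrow(px), ncol(px))
  rows <- seq_len(nrow(px))
  for (j in columns) {
    m[, j] <- rows > boundaries$rpe_bruch[j] & rows <= boundaries$choroid_sclera[j]
  }
  m
}

#' Macular subfield definition
#'
#' Strip of the B-scan at a given eccentricity range from the fovea, applied
#' symmetrically on both sides. Defaults follow the study subfields: inner
#' 0.5-1.0 mm, outer 1.0-1.5 mm.
#'
#' @param label `"inner"` or `"outer"`, or any custom label.
#' @param eccentricity_range `c(lower, upper)` in mm, `0 <= lower < upper`.
#' @return A list of class `subfield`.
#' @export
subfield <- function(label = c("inner", "outer"), eccentricity_range = NULL) {
  if (is.null(eccentricity_range) && label[1] %in% c("inner", "outer")) {
    label <- match.arg(label)
    eccentricity_range <- if (label == "inner") c(0.5, 1.0) else c(1.0, 1.5)
  }
  stopifnot(length(eccentricity_range) == 2,
            eccentricity_range[1] >= 0,
            eccentricity_range[1] < eccentricity_range[2])
  structure(list(label = label[1], eccentricity_range = eccentricity_range),
            class = "subfield")
}

# Columns of a scan falling in a subfield (both sides of the fovea pooled)
subfield_columns <- function(scan, sf) {
  ecc_mm <- abs(seq_len(ncol(scan$pixels)) - scan$fovea_column) *
    scan$lateral_scale / 1000
  which(ecc_mm >= sf$eccentricity_range[1] & ecc_mm < sf$eccentricity_range[2])
}

#' Choroidal thickness and vascularity in a subfield
#'
#' Pools the left and right strips of the subfield and reports choroidal
#' thickness (CT, um, mean per-column boundary separation times the axial
#' scale), total choroidal area (TCA, mm^2, pixel count times pixel area),
#' luminal area (LA, mm^2, on the lumen mask), stromal area
#' (SA = TCA - LA, exact in pixel counts), and the choroidal vascularity
#' index CVI = LA / TCA.
#'
#' @param scan A [bscan()] (linearized).
#' @param boundaries A [boundary_set()] with `rpe_bruch` and
#'   `choroid_sclera` (consistent with the scan, i.e. also linearized).
#' @param lumen_mask Logical matrix from [niblack_binarize()].
#' @param sf A [subfield()].
#' @return An object of class `choroid_quant` with fields `CT`, `LA`, `SA`,
#'   `TCA`, `CVI`, `n_pixels`, `n_lumen_pixels`, `subfield`.
#' @export
choroid_metrics <- function(scan, boundaries, lumen_mask, sf = subfield("inner")) {
  stopifnot(inherits(scan, "bscan"))
  cols <- subfield_columns(scan, sf)
  if (length(cols) == 0) stop("subfield columns do not exist on this scan")
  cm <- choroid_mask(scan, boundaries, cols)
  cm <- cm & !is.na(scan$pixels)
  n_tca <- sum(cm)
  n_la <- sum(cm & lumen_mask)
  pix_area_mm2 <- scan$lateral_scale * scan$axial_scale / 1e6
  tca <- n_tca * pix_area_mm2
  la <- n_la * pix_area_mm2
  sa <- (n_tca - n_la) * pix_area_mm2
  cvi <- if (n_tca == 0) NA_real_ else n_la / n_tca
  ct <- mean((boundaries$choroid_sclera[cols] - boundaries$rpe_bruch[cols])) *
    scan$axial_scale
  out <- list(CT = ct, LA = la, SA = sa, TCA = tca, CVI = cvi,
              n_pixels = n_tca, n_lumen_pixels = n_la,
              n_stroma_pixels = n_tca - n_la, subfield = sf$label)
  if (n_tca == 0) out$flag <- "empty_choroid"
  structure(out, class = "choroid_quant")
}

#' @export
print.choroid_quant <- function(x, ...) {
  cat(sprintf(
    "Choroid (%s): CT %.1f um, TCA %.4f mm^2, LA %.4f mm^2, CVI %.3f\n",
    x$subfield, x$CT, x$TCA, x$LA, x$CVI))
  invisible(x)
}

#' Outer-retinal sublayer thicknesses in a subfield
#'
#' Mean per-column depth difference between the bounding interfaces of each
#' requested layer over the subfield columns, converted to um. Layers are
#' OPL, HFL+ONL, IS, OS, and IZ+RPE, delimited by the interfaces documented
#' in [boundary_set()].
#'
#' @param scan A [bscan()] (supplies the axial scale, fovea column, width).
#' @param boundaries A [boundary_set()] with the interfaces of the
#'   requested layers.
#' @param sf A [subfield()].
#' @param layers Character vector of layer names to compute.
#' @return Named numeric vector of thicknesses in um.
#' @export
sublayer_thickness <- function(scan, boundaries, sf = subfield("inner"),
                               layers = names(.layer_map)) {
  cols <- subfield_columns(scan, sf)
  if (length(cols) == 0) stop("subfield columns do not exist on this scan")
  out <- vapply(layers, function(ln) {
    pair <- .layer_map[[ln]]
    if (is.null(pair)) stop("unknown layer: ", ln)
    up <- boundaries[[pair[1]]]; lo <- boundaries[[pair[2]]]
    if (is.null(up) || is.null(lo))
      stop("boundary pair for layer ", ln, " not present")
    mean(lo[cols] - up[cols]) * scan$axial_scale
  }, 0)
  names(out) <- layers
  out
}

#' Repeatability of paired measurements
#'
#' Coefficient of repeatability (CoR, 1.96 times the standard deviation of
#' the paired differences) and the intraclass correlation coefficient,
#' computed as two-way random effects, absolute agreement, single
#' measurement (ICC(2,1)) from the two-way ANOVA mean squares.
#'
#' @param m1,m2 Paired numeric series of equal length (>= 3).
#' @return List with `cor` (coefficient of repeatability), `icc`, `n`, and
#'   `flag` (set when ICC is undefined because both series are constant).
#' @export
agreement_stats <- function(m1, m2) {
  stopifnot(is.numeric(m1), is.numeric(m2), length(m1) == length(m2))
  n <- length(m1)
  if (n < 3) stop("need at least 3 paired measurements")
  d <- m1 - m2
  cor_rep <- 1.96 * stats::sd(d)
  if (stats::var(m1) == 0 && stats::var(m2) == 0) {
    return(list(cor = cor_rep, icc = NA_real_, n = n, flag = "zero_variance"))
  }
  k <- 2
  y <- cbind(m1, m2)
  grand <- mean(y)
  msr <- k * sum((rowMeans(y) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(y) - grand)^2) / (k - 1)
  sst <- sum((y - grand)^2)
  mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  list(cor = cor_rep, icc = icc, n = n, flag = NULL)
}

# --- box-filter primitive ---------------------------------------------------

# Sliding-window sum over a (w x w) window via integral images; windows are
# truncated at the borders (sums over the in-frame part only).
box_sum <- function(m, w) {
  r <- (w - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  # integral image with a zero row/col prefix
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - r, 1); r1 <- pmin(seq_len(nr) + r, nr)
  c0 <- pmax(seq_len(nc) - r, 1); c1 <- pmin(seq_len(nc) + r, nc)
  # S(a:b, c:d) = ii[b+1,d+1] - ii[a,d+1] - ii[b+1,c] + ii[a,c]
  ii[r1 + 1, c1 + 1] - ii[r0, c1 + 1] - ii[r1 + 1, c0] + ii[r0, c0]
}
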