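#' Eye biometry record
#'
#' Bundles the ocular biometry needed for magnification correction: axial
#' length (AL, mm), spherical equivalent refraction (SE, diopters) and,
#' optionally, intraocular pressure (mmHg).
#'
#' @param axial_length Axial length in mm; must lie in (15, 40).
#' @param spherical_equivalent Spherical equivalent in diopters; must lie in
#'   (-30, +15).
#' @param iop Intraocular pressure in mmHg (optional, recorded as-is).
#' @return An object of class `eye_biometry`.
#' @examples
#' eye_biometry(24.0, -1.25)
#' @export
eye_biometry <- function(axial_length, spherical_equivalent, iop = NA_real_) {
  stopifnot(is.numeric(axial_length), length(axial_length) == 1L,
            is.numeric(spherical_equivalent), length(spherical_equivalent) == 1L)
  if (!is.finite(axial_length) || axial_length <= 15 || axial_length >= 40)
    stop("axial_length must be in (15, 40) mm, got ", axial_length)
  if (!is.finite(spherical_equivalent) ||
      spherical_equivalent <= -30 || spherical_equivalent >= 15)
    stop("spherical_equivalent must be in (-30, +15) D, got ", spherical_equivalent)
  structure(list(axial_length = axial_length,
                 spherical_equivalent = spherical_equivalent,
                 iop = iop),
            class = "eye_biometry")
}

#' @export
print.eye_biometry <- function(x, ...) {
  cat(sprintf("Eye biometry: AL %.2f mm, SE %+.2f D", x$axial_length,
              x$spherical_equivalent))
  if (is.finite(x$iop)) cat(sprintf(", IOP %.1f mmHg", x$iop))
  cat("\n")
  invisible(x)
}

#' Axial-length magnification factor (Bennett's method)
#'
#' Computes the retinal scaling factor q (mm of retina per degree of visual
#' angle, up to the camera constant) from axial length as
#' `q = linear_coefficient * (AL - offset_mm)`. The default constants are the
#' standard ones for Bennett's axial-length method, which places the second
#' principal point 1.82 mm behind the cornea.
#'
#' @param biometry An [eye_biometry()] object, or a bare axial length in mm.
#' @param linear_coefficient Slope of the linear AL model, 1/mm.
#' @param offset_mm Distance from cornea to second principal point, mm.
#' @return An object of class `magnification_model` with fields `q_factor`,
#'   `axial_length`, `linear_coefficient`, `offset`.
#' @examples
#' bennett_q(24.0)$q_factor  # 0.28967
#' @export
bennett_q <- function(biometry, linear_coefficient = 0.01306, offset_mm = 1.82) {
  al <- if (inherits(biometry, "eye_biometry")) biometry$axial_length else biometry
  stopifnot(is.numeric(al), length(al) == 1L)
  if (!is.finite(al) || al <= 15 || al >= 40)
    stop("axial_length must be in (15, 40) mm, got ", al)
  q <- linear_coefficient * (al - offset_mm)
  if (q <= 0) stop("degenerate magnification model: q_factor must be positive")
  structure(list(q_factor = q,
                 axial_length = al,
                 linear_coefficient = linear_coefficient,
                 offset = offset_mm),
            class = "magnification_model")
}

#' Relative lateral scale between an eye and a reference eye
#'
#' Ratio by which physical (on-retina) lateral dimensions in an image of an
#' eye with axial length `AL` must be multiplied, relative to the device
#' calibration at a reference axial length:
#' `(AL - offset) / (reference_al - offset)`. Applies to lateral (transverse)
#' dimensions only; axial OCT dimensions are taken as optically calibrated.
#'
#' @param biometry An [eye_biometry()] object or a bare axial length in mm.
#' @param reference_al Reference axial length of the device calibration, mm.
#' @param offset_mm Bennett offset, mm.
#' @return Dimensionless scale ratio; exactly 1 when `AL == reference_al`.
#' @examples
#' scale_factor(26.77)  # SHM-length eye imaged on a 24 mm calibration
#' @export
scale_factor <- function(biometry, reference_al = 24.0, offset_mm = 1.82) {
  al <- if (inherits(biometry, "eye_biometry")) biometry$axial_length else biometry
  stopifnot(is.numeric(al), length(al) == 1L)
  if (!is.finite(al) || al <= 15 || al >= 40)
    stop("axial_length must be in (15, 40) mm, got ", al)
  if (!is.finite(reference_al) || reference_al <= 15 || reference_al >= 40)
    stop("reference_al must be in (15, 40) mm, got ", reference_al)
  if (abs(reference_al - offset_mm) < .Machine$double.eps * 100)
    stop("reference_al equals the Bennett offset; scale undefined")
  (al - offset_mm) / (reference_al - offset_mm)
}

#' Convert pixel to physical dimensions and back
#'
#' @param px,um Lengths in pixels / micrometers.
#' @param pixel_scale Device pixel pitch in um/pixel at the reference eye.
#' @param scale Relative scale from [scale_factor()] (1 for the reference eye).
#' @return Length in the other unit.
#' @export
px_to_um <- function(px, pixel_scale, scale = 1) px * pixel_scale * scale

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_scale, scale = 1) um / (pixel_scale * scale)
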