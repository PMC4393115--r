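#' Camera model
#'
#' Describes the EMCCD geometry and photon calibration used both by the
#' simulator (photons -> ADU) and by the localization pipeline (ADU ->
#' photons).  Defaults follow a typical dSTORM setup: 256 x 256 pixel frames
#' with a 0.1067 um pixel at the sample plane.
#'
#' @param pixel_um Pixel size at the sample plane in micrometres.
#' @param width,height Frame size in pixels.
#' @param offset CCD offset in ADU (subtracted before gain conversion).
#' @param gain Gain factor in photons per ADU.
#' @param exposure_ms Exposure label in milliseconds (metadata only).
#'
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' cam$pixel_nm
#' @export
camera_model <- function(pixel_um = 0.1067, width = 256L, height = 256L,
                         offset = 100, gain = 0.5, exposure_ms = 17) {
  stopifnot(pixel_um > 0, gain > 0, offset >= 0, width >= 1, height >= 1)
  structure(list(pixel_um = pixel_um, pixel_nm = pixel_um * 1000,
                 width = as.integer(width), height = as.integer(height),
                 offset = offset, gain = gain, exposure_ms = exposure_ms),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: %d x %d px, %.4f um/px, offset %g ADU, gain %g photons/ADU\n",
              x$width, x$height, x$pixel_um, x$offset, x$gain))
  invisible(x)
}

#' Convert raw camera counts to photons
#'
#' photons = max(0, (ADU - offset) * gain).  Values below the offset are
#' clamped to zero photons.
#'
#' @param frame Numeric matrix or 3D array of ADU values.
#' @param cam A [camera_model()].
#' @return Object of the same shape in photon units.
#' @examples
#' cam <- camera_model(offset = 100, gain = 0.45)
#' adu_to_photons(matrix(300, 1, 1), cam)  # 90 photons
#' @export
adu_to_photons <- function(frame, cam) {
  stopifnot(inherits(cam, "camera_model"))
  pmax((frame - cam$offset) * cam$gain, 0)  # first-arg attributes keep dim
}
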