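#' Reconstruct a super-resolution image from a localization table
#'
#' Every accepted localization is drawn as a unit-integral 2D Gaussian whose
#' standard deviations are the record's CRLB precisions, so the image mass
#' equals the number of rendered localizations (up to the 4-sigma
#' truncation).  Precisions smaller than a quarter SR pixel are floored at
#' 0.25 px and counted in the `n_floored` attribute.
#'
#' @param table Localization table with `x_nm`, `y_nm`, `sigma_x_nm`,
#'   `sigma_y_nm` (and `accepted` unless `accepted_only = FALSE`).
#' @param pixel_nm SR grid pixel size (nm).
#' @param field_nm Grid extent `c(width, height)` nm; defaults to the bounding
#'   box of the table padded by 4 times the largest precision.
#' @param origin_nm Grid origin (nm), default `c(0, 0)`.
#' @param accepted_only Render only rows with `accepted == TRUE`.
#' @return An `sr_image`: numeric matrix with `pixel_nm`, `origin_nm`,
#'   `n_rendered` and `n_floored` attributes.
#' @export
render_sr <- function(table, pixel_nm = 10, field_nm = NULL,
                      origin_nm = c(0, 0), accepted_only = TRUE) {
  stopifnot(pixel_nm > 0)
  if (accepted_only && "accepted" %in% names(table))
    table <- table[table$accepted, , drop = FALSE]
  if (is.null(field_nm)) {
    if (nrow(table) == 0) field_nm <- c(pixel_nm, pixel_nm)
    else {
      pad <- 4 * max(table$sigma_x_nm, table$sigma_y_nm, pixel_nm)
      field_nm <- c(max(table$x_nm) - origin_nm[1] + pad,
                    max(table$y_nm) - origin_nm[2] + pad)
    }
  }
  field_nm <- rep(field_nm, length.out = 2)
  nx <- as.integer(ceiling(field_nm[1] / pixel_nm))
  ny <- as.integer(ceiling(field_nm[2] / pixel_nm))
  if (nrow(table) == 0) {
    img <- matrix(0, nx, ny)
    n_floored <- 0L
  } else {
    sx <- pmax(table$sigma_x_nm / pixel_nm, 0.25)
    sy <- pmax(table$sigma_y_nm / pixel_nm, 0.25)
    n_floored <- sum(table$sigma_x_nm / pixel_nm < 0.25 |
                     table$sigma_y_nm / pixel_nm < 0.25)
    if (n_floored > 0)
      warning(sprintf("%d localization(s) below 0.25 SR px precision; floored",
                      n_floored))
    img <- cpp_render_sr(nx, ny,
                         (table$x_nm - origin_nm[1]) / pixel_nm,
                         (table$y_nm - origin_nm[2]) / pixel_nm, sx, sy)
  }
  structure(img, pixel_nm = pixel_nm, origin_nm = origin_nm,
            n_rendered = nrow(table), n_floored = n_floored,
            class = c("sr_image", "matrix", "array"))
}

#' Compose single-color SR images into an RGB overlay
#'
#' Each image is normalized to \[0, 1\] by its maximum, multiplied by its
#' 3-digit color index \[R, G, B\], and the color-encoded images are summed.
#' Pixels whose summed index exceeds \[1, 1, 1\] are divided by their maximum
#' channel, keeping all output channels in \[0, 1\].  Typical indices:
#' \[1,1,0\] clathrin, \[0,1,0\] tubulin, \[0.8,0.2,0\] actin, \[0,0.5,1\]
#' EGFR; \[1,0,1\]/\[0,1,0\] for two-color magenta/green.
#'
#' @param images List of equal-sized [render_sr()] images (or matrices).
#' @param indices List of numeric length-3 color indices with digits in
#'   \[0, 1\].
#' @return An `overlay_image`: `nx x ny x 3` array with values in \[0, 1\].
#' @export
overlay <- function(images, indices) {
  stopifnot(length(images) >= 1, length(images) == length(indices))
  d <- dim(images[[1]])[1:2]
  for (im in images) stopifnot(all(dim(im)[1:2] == d))
  for (ci in indices) stopifnot(length(ci) == 3, all(ci >= 0), all(ci <= 1))
  rgb <- array(0, dim = c(d[1], d[2], 3))
  for (k in seq_along(images)) {
    v <- unclass(images[[k]])
    mx <- max(v)
    if (mx > 0) v <- v / mx
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] + indices[[k]][ch] * v
  }
  peak <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  scale <- ifelse(peak > 1, peak, 1)
  for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] / scale
  structure(rgb, class = c("overlay_image", "array"))
}

#' Scale image contrast
#'
#' Multiplies pixel values by `factor` and clips at the display maximum
#' (used e.g. to boost post-photodestruction residual images 3x).
#'
#' @param image Numeric matrix or array.
#' @param factor Positive scale factor.
#' @param display_max Clip ceiling; defaults to the image maximum.
#' @return Scaled image of the same class.
#' @export
contrast_scale <- function(image, factor, display_max = max(image)) {
  stopifnot(factor > 0)
  out <- pmin(image * factor, display_max)
  attributes(out) <- attributes(image)
  out
}
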