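#' Build subregions for cross-talk estimation
#'
#' Places a regular grid of `box_nm`-sized axis-aligned boxes over the
#' bounding box of the "before" table and keeps boxes containing at least
#' `min_before` accepted localizations (a density mask standing in for the
#' usual hand-picked ~2 x 2 um subregions).
#'
#' @param before Localization table defining the density mask.
#' @param box_nm Box side length (nm).
#' @param min_before Minimum accepted "before" localizations per box.
#' @param accepted_only Count only accepted localizations.
#' @return Data frame of boxes (`x0`, `y0`, `x1`, `y1`, `n_before`).
#' @export
subregion_grid <- function(before, box_nm = 2000, min_before = 50,
                           accepted_only = TRUE) {
  if (accepted_only && "accepted" %in% names(before))
    before <- before[before$accepted, , drop = FALSE]
  if (!nrow(before)) stop("no localizations to place subregions on")
  xs <- seq(floor(min(before$x_nm) / box_nm) * box_nm, max(before$x_nm), by = box_nm)
  ys <- seq(floor(min(before$y_nm) / box_nm) * box_nm, max(before$y_nm), by = box_nm)
  boxes <- expand.grid(x0 = xs, y0 = ys)
  boxes$x1 <- boxes$x0 + box_nm
  boxes$y1 <- boxes$y0 + box_nm
  boxes$n_before <- mapply(function(x0, y0, x1, y1)
    sum(before$x_nm >= x0 & before$x_nm < x1 &
        before$y_nm >= y0 & before$y_nm < y1),
    boxes$x0, boxes$y0, boxes$x1, boxes$y1)
  boxes[boxes$n_before >= min_before, , drop = FALSE]
}

#' Estimate inter-round cross-talk from localization counts
#'
#' Cross-talk is the percentage of localized emitters remaining after
#' photodestruction, relative to the initial image, evaluated per subregion:
#' `100 * n_after / n_before`.  Boxes below the minimum "before" count are
#' excluded.
#'
#' @param before,after Localization tables in the same coordinate frame.
#' @param regions Optional data frame of boxes (`x0`,`y0`,`x1`,`y1`);
#'   defaults to [subregion_grid()] on `before`.
#' @param box_nm,min_before Passed to [subregion_grid()] when `regions` is
#'   NULL.
#' @param accepted_only Count only accepted localizations.
#' @return A `crosstalk_report` list: `regions` (per-box counts and
#'   percentage), `mean_pct`, `median_pct`, `n_regions`.
#' @export
crosstalk <- function(before, after, regions = NULL, box_nm = 2000,
                      min_before = 50, accepted_only = TRUE) {
  if (accepted_only && "accepted" %in% names(before))
    before <- before[before$accepted, , drop = FALSE]
  if (accepted_only && "accepted" %in% names(after))
    after <- after[after$accepted, , drop = FALSE]
  if (is.null(regions))
    regions <- subregion_grid(before, box_nm, min_before, accepted_only = FALSE)
  if (!nrow(regions)) stop("no subregion meets the minimum before-count")
  cnt <- function(tab, x0, y0, x1, y1)
    sum(tab$x_nm >= x0 & tab$x_nm < x1 & tab$y_nm >= y0 & tab$y_nm < y1)
  regions$n_before <- mapply(cnt, regions$x0, regions$y0, regions$x1,
                             regions$y1, MoreArgs = list(tab = before))
  regions$n_after <- mapply(cnt, regions$x0, regions$y0, regions$x1,
                            regions$y1, MoreArgs = list(tab = after))
  keep <- regions$n_before > 0
  regions <- regions[keep, , drop = FALSE]
  regions$pct <- 100 * regions$n_after / regions$n_before
  structure(list(regions = regions, mean_pct = mean(regions$pct),
                 median_pct = median(regions$pct),
                 n_regions = nrow(regions)),
            class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat(sprintf("crosstalk_report: %d subregions, mean %.3f%%, median %.3f%%\n",
              x$n_regions, x$mean_pct, x$median_pct))
  invisible(x)
}

#' Magnitude of a 2D shift
#'
#' @param dx,dy Shift components (nm).
#' @return Euclidean magnitude `sqrt(dx^2 + dy^2)`.
#' @export
shift_magnitude <- function(dx, dy) sqrt(dx^2 + dy^2)

#' Global shift between two SR reconstructions
#'
#' Subpixel Fourier cross-correlation (same estimator as the brightfield
#' x-y alignment) on the two rendered images, scaled to nm by the SR pixel
#' size.  Returns the displacement of `imageB` relative to `imageA`.
#'
#' @param imageA,imageB [render_sr()] images on the same grid.
#' @return List: `dx`, `dy`, `magnitude` (nm), `flag`.
#' @export
global_shift <- function(imageA, imageB) {
  stopifnot(all(dim(imageA) == dim(imageB)))
  if (max(imageA) == min(imageA) || max(imageB) == min(imageB))
    stop("featureless image in global_shift()")
  px <- attr(imageA, "pixel_nm") %||% 1
  sh <- find_xy_shift(unclass(imageB), unclass(imageA), pixel_nm = px)
  list(dx = sh$dx, dy = sh$dy,
       magnitude = shift_magnitude(sh$dx, sh$dy), flag = sh$flag)
}

#' Microtubule segment specification
#'
#' Two endpoints chosen top to bottom on an approximately linear structure
#' define a rotated rectangle: length along the segment, `half_width_nm` on
#' each side across it.  The rotation angle is `atan2(y2 - y1, x2 - x1)`
#' (the arctangent of the slope), so rotating localizations by its negative
#' puts the segment along the x axis.
#'
#' @param x1,y1,x2,y2 Segment endpoints (nm).
#' @param half_width_nm Rectangle half width across the segment (nm).
#' @param bin_nm Profile histogram bin width (nm).
#' @param min_locs Minimum localizations required per channel.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(x1, y1, x2, y2, half_width_nm = 150, bin_nm = 5,
                         min_locs = 100) {
  stopifnot(!(x1 == x2 && y1 == y2), half_width_nm > 0, bin_nm > 0)
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 half_width_nm = half_width_nm, bin_nm = bin_nm,
                 min_locs = min_locs,
                 angle = atan2(y2 - y1, x2 - x1),
                 length_nm = sqrt((x2 - x1)^2 + (y2 - y1)^2)),
            class = "segment_spec")
}

# least-squares 3-parameter Gaussian fit to a binned profile
fit_gaussian_profile <- function(centers, counts, half_width) {
  tot <- sum(counts)
  if (tot <= 0) return(list(amplitude = NA, mean = NA, sigma = NA,
                            flag = "empty profile"))
  mu0 <- sum(centers * counts) / tot
  s0 <- sqrt(max(sum(counts * (centers - mu0)^2) / tot, 1))
  df <- data.frame(y = counts, x = centers)
  fit <- tryCatch(
    nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
        start = list(A = max(counts), mu = mu0, s = s0),
        lower = c(1e-9, -half_width, 0.5), upper = c(Inf, half_width, Inf),
        algorithm = "port", control = nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(amplitude = max(counts), mean = mu0, sigma = s0,
                flag = "fit failed; moment estimates"))
  cf <- coef(fit)
  flag <- if (cf[["s"]] > half_width) "sigma exceeds half width" else ""
  list(amplitude = cf[["A"]], mean = cf[["mu"]], sigma = cf[["s"]],
       flag = flag)
}

#' Local overlay shift across a linear segment
#'
#' Selects the localizations of both channels inside the segment rectangle,
#' rotates them so the segment lies along the x axis, histograms the
#' perpendicular (y) coordinates in `bin_nm` bins across the full rectangle
#' width (zero-count bins retained), fits a 3-parameter Gaussian to each
#' channel's profile and reports the difference of the fitted means
#' (`channel B - channel A`; positive = B displaced toward increasing
#' rotated-perpendicular coordinate).
#'
#' @param tableA,tableB Localization tables (accepted rows used when an
#'   `accepted` column is present).
#' @param seg A [segment_spec()].
#' @return List: `shift_nm`, per-channel `fits`, `n` (per-channel counts
#'   inside the rectangle), `flag`, and the binned `profiles`.
#' @export
local_shift <- function(tableA, tableB, seg) {
  stopifnot(inherits(seg, "segment_spec"))
  sel <- function(tab) {
    if ("accepted" %in% names(tab)) tab <- tab[tab$accepted, , drop = FALSE]
    ca <- cos(seg$angle); sa <- sin(seg$angle)
    u <- ca * (tab$x_nm - seg$x1) + sa * (tab$y_nm - seg$y1)
    v <- -sa * (tab$x_nm - seg$x1) + ca * (tab$y_nm - seg$y1)
    keep <- u >= 0 & u <= seg$length_nm & abs(v) <= seg$half_width_nm
    v[keep]
  }
  vA <- sel(tableA); vB <- sel(tableB)
  if (length(vA) < seg$min_locs || length(vB) < seg$min_locs)
    stop(sprintf("segment has too few localizations (A: %d, B: %d, need %d)",
                 length(vA), length(vB), seg$min_locs))
  breaks <- seq(-seg$half_width_nm, seg$half_width_nm, by = seg$bin_nm)
  if (tail(breaks, 1) < seg$half_width_nm)
    breaks <- c(breaks, seg$half_width_nm)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  hA <- hist_counts(vA, breaks)
  hB <- hist_counts(vB, breaks)
  fA <- fit_gaussian_profile(centers, hA, seg$half_width_nm)
  fB <- fit_gaussian_profile(centers, hB, seg$half_width_nm)
  flag <- paste(c(if (nzchar(fA$flag)) paste0("A: ", fA$flag),
                  if (nzchar(fB$flag)) paste0("B: ", fB$flag)), collapse = "; ")
  list(shift_nm = fB$mean - fA$mean, fits = list(A = fA, B = fB),
       n = c(A = length(vA), B = length(vB)), flag = flag,
       profiles = data.frame(center_nm = centers, countA = hA, countB = hB))
}

hist_counts <- function(v, breaks) {
  idx <- findInterval(v, breaks)
  idx[idx >= length(breaks)] <- length(breaks) - 1L  # right edge closed
  idx <- idx[idx >= 1L]
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' Global and per-segment shift report for a two-round experiment
#'
#' Renders both tables on a shared SR grid, estimates the global shift by
#' image cross-correlation, and the local shift of every segment by the
#' rotation + perpendicular Gaussian-profile procedure.  Each segment also
#' gets a display arrow along its perpendicular axis with length equal to
#' the signed shift.
#'
#' @param tableA,tableB Localization tables in the same coordinate frame.
#' @param segments List of [segment_spec()]s.
#' @param pixel_nm SR grid pixel for the global estimate.
#' @param field_nm Optional shared grid extent (nm).
#' @return A `shift_report`: `global` (dx, dy, magnitude), `segments` data
#'   frame (endpoints, angle, signed shift, arrow components, flags) and the
#'   per-segment fit details.
#' @export
shift_report <- function(tableA, tableB, segments, pixel_nm = 10,
                         field_nm = NULL) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  if (is.null(field_nm)) {
    all_xy <- rbind(tableA[c("x_nm", "y_nm")], tableB[c("x_nm", "y_nm")])
    field_nm <- c(max(all_xy$x_nm), max(all_xy$y_nm)) + 4 * pixel_nm
  }
  imgA <- render_sr(tableA, pixel_nm = pixel_nm, field_nm = field_nm)
  imgB <- render_sr(tableB, pixel_nm = pixel_nm, field_nm = field_nm)
  gl <- global_shift(imgA, imgB)
  details <- lapply(segments, function(s) local_shift(tableA, tableB, s))
  seg_df <- do.call(rbind, lapply(seq_along(segments), function(k) {
    s <- segments[[k]]; d <- details[[k]]
    perp <- c(-sin(s$angle), cos(s$angle))
    data.frame(segment = k, x1 = s$x1, y1 = s$y1, x2 = s$x2, y2 = s$y2,
               angle = s$angle, shift_nm = d$shift_nm,
               arrow_dx = d$shift_nm * perp[1], arrow_dy = d$shift_nm * perp[2],
               nA = d$n["A"], nB = d$n["B"], flag = d$flag,
               row.names = NULL)
  }))
  structure(list(global = gl, segments = seg_df, details = details),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("shift_report: global (%.2f, %.2f) nm, |%.2f| nm; %d segment(s), median |local| %.2f nm\n",
              x$global$dx, x$global$dy, x$global$magnitude,
              nrow(x$segments), median(abs(x$segments$shift_nm))))
  invisible(x)
}
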