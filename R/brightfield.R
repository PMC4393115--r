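#' Synthetic brightfield volume with known 3D pose
#'
#' Generates a band-limited 3D intensity texture standing in for the
#' brightfield contrast of a cell: seeded white noise smoothed by a separable
#' Gaussian (correlation length ~1 um laterally, ~10 z-steps axially), offset
#' to strictly positive intensities.  The smoothness guarantees a unique,
#' well-behaved normalized cross-correlation peak for shifts inside the
#' search range.  The default lateral size matches the native 256 x 256
#' brightfield frame; the z-peak quadratic fit averages realization
#' asymmetry over independent lateral patches, and markedly smaller fields
#' leave a texture-dependent z bias that can exceed the 10 nm tolerance.
#' The lateral extent carries a margin so the volume can be sampled at
#' non-zero poses; [sample_brightfield()] returns the central `nx x ny`
#' crop.
#'
#' @param nx,ny Sampled image size in pixels.
#' @param nz Number of z planes.
#' @param pixel_nm Lateral grid spacing (nm).
#' @param dz_nm Axial grid spacing (nm).
#' @param corr_xy_nm Lateral correlation length (Gaussian sigma, nm).
#' @param corr_z_steps Axial correlation length in z-steps.
#' @param margin_px Lateral margin (pixels) allowing in-plane pose shifts.
#' @param seed RNG seed.
#' @return A `brightfield_volume` (3D array with grid metadata attributes).
#' @export
brightfield_volume <- function(nx = 256, ny = 256, nz = 61,
                               pixel_nm = 106.7, dz_nm = 50,
                               corr_xy_nm = 1000, corr_z_steps = 10,
                               margin_px = 10, seed = NULL) {
  stopifnot(nx > 0, ny > 0, nz > 2, pixel_nm > 0, dz_nm > 0)
  NX <- nx + 2L * margin_px; NY <- ny + 2L * margin_px
  with_seed(seed, {
    v <- array(rnorm(NX * NY * nz), dim = c(NX, NY, nz))
    v <- gauss_smooth_3d(v, c(corr_xy_nm / pixel_nm, corr_xy_nm / pixel_nm,
                              corr_z_steps))
    v <- v / sd(v)
    v <- 1000 + 200 * v
    v[v < 1] <- 1
    structure(v, pixel_nm = pixel_nm, dz_nm = dz_nm,
              nx = as.integer(nx), ny = as.integer(ny),
              margin_px = as.integer(margin_px),
              z0 = (nz - 1) / 2,
              class = c("brightfield_volume", "array"))
  })
}

# separable Gaussian smoothing with periodic boundaries (FFT along each dim)
gauss_smooth_3d <- function(v, sigmas) {
  d <- dim(v)
  for (ax in 1:3) {
    s <- sigmas[ax]
    if (s <= 0) next
    n <- d[ax]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    ker <- exp(-0.5 * (x / s)^2)
    ker <- ker / sum(ker)
    K <- Re(fft(ker))
    perm <- c(ax, setdiff(1:3, ax))
    vp <- aperm(v, perm)
    m <- matrix(vp, nrow = n)
    sm <- Re(mvfft(mvfft(m) * K, inverse = TRUE)) / n
    vp <- array(sm, dim = d[perm])
    v <- aperm(vp, order(perm))
  }
  v
}

#' Wrap a plain 3D array as a brightfield volume
#'
#' Attaches the grid metadata needed by [sample_brightfield()] to an
#' existing intensity array (e.g. one read back from a TIFF z-stack).
#'
#' @param arr 3D array `(nx + 2*margin_px, ny + 2*margin_px, nz)`.
#' @param pixel_nm,dz_nm Grid spacings (nm).
#' @param margin_px Lateral margin reserved for pose shifts.
#' @return A `brightfield_volume`.
#' @export
as_brightfield_volume <- function(arr, pixel_nm = 106.7, dz_nm = 50,
                                  margin_px = 0) {
  stopifnot(length(dim(arr)) == 3, all(arr > 0))
  structure(arr, pixel_nm = pixel_nm, dz_nm = dz_nm,
            nx = as.integer(dim(arr)[1] - 2 * margin_px),
            ny = as.integer(dim(arr)[2] - 2 * margin_px),
            margin_px = as.integer(margin_px), z0 = (dim(arr)[3] - 1) / 2,
            class = c("brightfield_volume", "array"))
}

#' Rigid 3D pose
#'
#' Translation of the sample relative to the reference position, in nm.
#' @param dx,dy,dz Translation components (nm).
#' @return Named numeric vector of class `pose3d`.
#' @export
pose3d <- function(dx = 0, dy = 0, dz = 0) {
  structure(c(dx = dx, dy = dy, dz = dz), class = "pose3d")
}

#' Sample a brightfield image at a given pose
#'
#' Trilinear interpolation of the volume at the lateral/axial position given
#' by `pose`; deterministic.  `pose = c(0,0,0)` returns exactly the central
#' reference slice.
#'
#' @param vol A [brightfield_volume()].
#' @param pose A [pose3d()] or numeric `c(dx, dy, dz)` in nm.
#' @return `nx x ny` image matrix.
#' @export
sample_brightfield <- function(vol, pose = pose3d()) {
  stopifnot(inherits(vol, "brightfield_volume"))
  pose <- as.numeric(pose)
  px <- attr(vol, "pixel_nm"); dznm <- attr(vol, "dz_nm")
  nx <- attr(vol, "nx"); ny <- attr(vol, "ny")
  mar <- attr(vol, "margin_px"); z0 <- attr(vol, "z0")
  d <- dim(vol)
  gx <- mar + (0:(nx - 1)) + pose[1] / px
  gy <- mar + (0:(ny - 1)) + pose[2] / px
  gz <- z0 + pose[3] / dznm
  if (min(gx) < 0 || max(gx) > d[1] - 1 || min(gy) < 0 || max(gy) > d[2] - 1 ||
      gz < 0 || gz > d[3] - 1)
    stop("pose outside the interpolable range of the volume")
  k0 <- min(floor(gz), d[3] - 2); wz <- gz - k0
  slice <- vol[, , k0 + 1] * (1 - wz) + vol[, , k0 + 2] * wz
  i0 <- pmin(floor(gx), d[1] - 2); wx <- gx - i0
  j0 <- pmin(floor(gy), d[2] - 2); wy <- gy - j0
  r0 <- i0 + 1; r1 <- i0 + 2; c0 <- j0 + 1; c1 <- j0 + 2
  top <- slice[r0, c0] * (1 - wx) + slice[r1, c0] * wx
  bot <- slice[r0, c1] * (1 - wx) + slice[r1, c1] * wx
  sweep(top, 2, 1 - wy, "*") + sweep(bot, 2, wy, "*")
}
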