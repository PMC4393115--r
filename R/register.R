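#' Registration configuration
#'
#' Parameters of the iterative brightfield alignment: a z-scan of 21 slices
#' from -500 nm to +500 nm in 50 nm steps, a quadratic fit through the 9
#' largest (consecutive) normalized cross-correlation points, and
#' convergence tolerances of 5 nm in x and y and 10 nm in z.
#'
#' @param half_range_nm Half extent of the z scan (nm).
#' @param step_nm z step (nm); must divide the half range.
#' @param n_fit Number of NCC points used for the quadratic peak fit.
#' @param tol_xy_nm,tol_z_nm Per-iteration adjustment tolerances (nm).
#' @param max_iter Maximum outer iterations.
#' @return An object of class `register_config`.
#' @export
register_config <- function(half_range_nm = 500, step_nm = 50, n_fit = 9,
                            tol_xy_nm = 5, tol_z_nm = 10, max_iter = 10) {
  stopifnot(half_range_nm > 0, step_nm > 0,
            abs(half_range_nm / step_nm - round(half_range_nm / step_nm)) < 1e-9,
            n_fit >= 3, tol_xy_nm > 0, tol_z_nm > 0, max_iter >= 1)
  structure(list(half_range_nm = half_range_nm, step_nm = step_nm,
                 n_fit = as.integer(n_fit), tol_xy_nm = tol_xy_nm,
                 tol_z_nm = tol_z_nm, max_iter = as.integer(max_iter)),
            class = "register_config")
}

#' z positions of the default registration scan
#'
#' @param cfg A [register_config()].
#' @return Vector of relative z positions (nm); 21 values by default.
#' @export
zscan_positions <- function(cfg = register_config()) {
  seq(-cfg$half_range_nm, cfg$half_range_nm, by = cfg$step_nm)
}

#' Normalized cross-correlation of two images
#'
#' Pearson correlation of the mean-subtracted, norm-divided pixel vectors;
#' a value in \[-1, 1\].
#'
#' @param image,reference Equal-sized matrices.
#' @return Scalar NCC.
#' @export
ncc <- function(image, reference) {
  stopifnot(all(dim(image) == dim(reference)))
  a <- as.numeric(image) - mean(image)
  b <- as.numeric(reference) - mean(reference)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero-variance image in ncc()")
  sum(a * b) / (na * nb)
}

#' Estimate the z offset from an NCC z-scan
#'
#' Computes the NCC of every slice against the reference, takes the `n_fit`
#' consecutive points centred on the argmax (window shifted to stay inside
#' the scan at the range ends), fits a second-order polynomial and returns
#' the vertex.  A concave-up fit or a vertex falling outside the fit window
#' is flagged and the argmax position returned instead.
#'
#' @param zstack 3D array or list of slice images.
#' @param z_positions Relative z of each slice (nm).
#' @param reference Reference image.
#' @param cfg A [register_config()].
#' @return List: `z` (nm), `ncc` (per-slice values), `flag` (character, ""
#'   when the fit was used).
#' @export
find_z <- function(zstack, z_positions, reference, cfg = register_config()) {
  slices <- if (is.list(zstack)) zstack else
    lapply(seq_len(dim(zstack)[3]), function(k) zstack[, , k])
  stopifnot(length(slices) == length(z_positions))
  nccs <- vapply(slices, ncc, numeric(1), reference = reference)
  m <- length(nccs)
  k <- min(cfg$n_fit, m)
  imax <- which.max(nccs)
  lo <- imax - (k - 1L) %/% 2L
  lo <- max(1L, min(lo, m - k + 1L))
  win <- lo:(lo + k - 1L)
  fit <- lm(nccs[win] ~ z_positions[win] + I(z_positions[win]^2))
  cf <- coef(fit)
  flag <- ""
  if (!is.finite(cf[3]) || cf[3] >= 0) {
    flag <- "concave-up fit"
    z <- z_positions[imax]
  } else {
    z <- -cf[2] / (2 * cf[3])
    if (z < min(z_positions[win]) || z > max(z_positions[win])) {
      flag <- "vertex outside fit window"
      z <- z_positions[imax]
    }
  }
  list(z = unname(z), ncc = nccs, flag = flag)
}

# NCC of the overlapping region when `image` content is displaced by
# (sx, sy) integer pixels relative to `reference` (no circular wrap).
ncc_at_shift <- function(image, reference, sx, sy) {
  nx <- nrow(image); ny <- ncol(image)
  ix <- (1 + max(0, sx)):(nx + min(0, sx))
  iy <- (1 + max(0, sy)):(ny + min(0, sy))
  if (length(ix) < 2 || length(iy) < 2) return(NA_real_)
  ncc(image[ix, iy, drop = FALSE],
      reference[ix - sx, iy - sy, drop = FALSE])
}

# bilinear sample of matrix m at fractional (0-based) coordinates gx x gy
bilinear_sample <- function(m, gx, gy) {
  i0 <- floor(gx); j0 <- floor(gy)
  wx <- gx - i0; wy <- gy - j0
  top <- m[i0 + 1, j0 + 1, drop = FALSE] * (1 - wx) +
         m[i0 + 2, j0 + 1, drop = FALSE] * wx
  bot <- m[i0 + 1, j0 + 2, drop = FALSE] * (1 - wx) +
         m[i0 + 2, j0 + 2, drop = FALSE] * wx
  sweep(top, 2, 1 - wy, "*") + sweep(bot, 2, wy, "*")
}

# Gauss-Newton subpixel refinement of the shift about integer (sx, sy):
# minimize || image(x) - reference(x - s - d) ||^2 over d on the overlap
# interior.  Unbiased for small d on smooth images, unlike the parabola.
refine_shift_gn <- function(image, reference, sx, sy, max_iter = 5) {
  nx <- nrow(image); ny <- ncol(image)
  mar <- 3
  ix <- (1 + max(0, sx) + mar):(nx + min(0, sx) - mar)
  iy <- (1 + max(0, sy) + mar):(ny + min(0, sy) - mar)
  if (length(ix) < 8 || length(iy) < 8) return(NULL)
  img_ov <- image[ix, iy]
  d <- c(0, 0)
  for (k in seq_len(max_iter)) {
    gx0 <- ix - 1 - sx - d[1]; gy0 <- iy - 1 - sy - d[2]
    if (min(gx0) < 1 || max(gx0) > nrow(reference) - 3 ||
        min(gy0) < 1 || max(gy0) > ncol(reference) - 3) return(NULL)
    refS <- bilinear_sample(reference, gx0, gy0)
    gxd <- (bilinear_sample(reference, gx0 + 0.5, gy0) -
            bilinear_sample(reference, gx0 - 0.5, gy0))
    gyd <- (bilinear_sample(reference, gx0, gy0 + 0.5) -
            bilinear_sample(reference, gx0, gy0 - 0.5))
    r <- as.numeric(img_ov - refS)
    G <- cbind(as.numeric(gxd), as.numeric(gyd))
    upd <- tryCatch(solve(crossprod(G), crossprod(G, r)), error = function(e) NULL)
    if (is.null(upd) || !all(is.finite(upd))) return(NULL)
    # image(x) = ref(x - s - d): residual decreases along -gradient direction
    d <- d - as.numeric(upd)
    if (max(abs(upd)) < 1e-4) break
  }
  if (max(abs(d)) > 1.5) return(NULL)  # diverged; caller falls back
  d
}

#' Subpixel x-y shift between two images
#'
#' Cross-correlation via the Fourier method locates the integer peak
#' (hill-climbing on the overlap-region normalized cross-correlation guards
#' against off-by-a-few peaks on smooth scenes); the fractional part is then
#' estimated by Gauss-Newton minimization of the resampled intensity
#' difference, falling back to 3-point parabolic interpolation of the NCC if
#' the refinement fails.  Returns the displacement of `image` relative to
#' `reference`: positive `dx` means the content of `image` sits at larger x
#' than in `reference`.
#'
#' @param image,reference Equal-sized matrices.
#' @param pixel_nm Pixel size used to scale the result to nm.
#' @return List: `dx`, `dy` (nm), `dx_px`, `dy_px`, `flag`.
#' @export
find_xy_shift <- function(image, reference, pixel_nm = 106.7) {
  stopifnot(all(dim(image) == dim(reference)))
  nx <- nrow(image); ny <- ncol(image)
  a <- image - mean(image); b <- reference - mean(reference)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  sx <- pk[1] - 1; if (sx > nx / 2) sx <- sx - nx
  sy <- pk[2] - 1; if (sy > ny / 2) sy <- sy - ny
  flag <- ""
  if (abs(sx) > nx / 4 || abs(sy) > ny / 4) {
    flag <- "peak near border"
    return(list(dx = sx * pixel_nm, dy = sy * pixel_nm,
                dx_px = sx, dy_px = sy, flag = flag))
  }
  # the FFT peak can be off by a few pixels on very smooth scenes: hill-climb
  # on the overlap-region NCC until the 3 x 3 neighborhood peaks at its centre
  nccL <- function(u, v) ncc_at_shift(image, reference, sx + u, sy + v)
  local <- outer(-1:1, -1:1, Vectorize(nccL))
  for (step in 1:16) {
    ctr <- arrayInd(which.max(local), dim(local)) - 2L
    if (all(ctr == 0L)) break
    sx <- sx + ctr[1]; sy <- sy + ctr[2]
    local <- outer(-1:1, -1:1, Vectorize(nccL))
  }
  d <- if (1 - local[2, 2] < 1e-12) c(0, 0) else
    refine_shift_gn(image, reference, sx, sy)
  if (is.null(d)) {
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (!is.finite(den) || den >= 0)
        return(list(d = 0, flag = "flat correlation peak"))
      list(d = max(-1, min(1, 0.5 * (cm - cp) / den)), flag = "")
    }
    px <- para(local[1, 2], local[2, 2], local[3, 2])
    py <- para(local[2, 1], local[2, 2], local[2, 3])
    d <- c(px$d, py$d)
    flag <- paste(c("parabolic fallback",
                    c(px$flag, py$flag)[nzchar(c(px$flag, py$flag))]),
                  collapse = "; ")
  }
  dx_px <- sx + d[1]; dy_px <- sy + d[2]
  list(dx = dx_px * pixel_nm, dy = dy_px * pixel_nm,
       dx_px = dx_px, dy_px = dy_px, flag = flag)
}

#' Iterative 3D brightfield alignment
#'
#' Simulates the stage-alignment loop: acquire a 21-slice z-stack about the
#' current pose, correct z from the quadratic NCC peak, acquire an image at
#' the corrected pose and correct x-y from the subpixel image shift; repeat
#' until every per-iteration adjustment is below tolerance or `max_iter` is
#' reached.  Stage moves are exact.
#'
#' @param vol A [brightfield_volume()].
#' @param reference Reference image (typically
#'   `sample_brightfield(vol, pose3d())`).
#' @param initial_pose Starting pose of the sample relative to the reference
#'   ([pose3d()] or numeric nm triple).
#' @param cfg A [register_config()].
#' @return A `registration_result` list: `pose` (final residual pose, nm),
#'   `correction` (total stage correction applied), `history` (one row per
#'   iteration of adjustments), `ncc` (final peak NCC), `converged`,
#'   `iterations`.
#' @export
align <- function(vol, reference, initial_pose = pose3d(),
                  cfg = register_config()) {
  pose <- as.numeric(initial_pose)
  zs <- zscan_positions(cfg)
  px <- attr(vol, "pixel_nm")
  hist <- matrix(NA_real_, nrow = 0, ncol = 3,
                 dimnames = list(NULL, c("adj_x", "adj_y", "adj_z")))
  converged <- FALSE
  flag <- ""
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    slices <- lapply(zs, function(z) sample_brightfield(vol, pose + c(0, 0, z)))
    fz <- find_z(slices, zs, reference, cfg)
    imax <- which.max(fz$ncc)
    if (imax == 1L || imax == length(fz$ncc)) {
      # NCC still rising at the scan end: the true z peak was not captured
      flag <- "z peak outside scan range"
      break
    }
    pose[3] <- pose[3] + fz$z
    img <- sample_brightfield(vol, pose)
    sh <- find_xy_shift(img, reference, pixel_nm = px)
    pose[1] <- pose[1] + sh$dx
    pose[2] <- pose[2] + sh$dy
    hist <- rbind(hist, c(sh$dx, sh$dy, fz$z))
    if (abs(sh$dx) < cfg$tol_xy_nm && abs(sh$dy) < cfg$tol_xy_nm &&
        abs(fz$z) < cfg$tol_z_nm) { converged <- TRUE; break }
  }
  final_ncc <- ncc(sample_brightfield(vol, pose), reference)
  structure(list(pose = pose3d(pose[1], pose[2], pose[3]),
                 correction = pose3d(pose[1] - as.numeric(initial_pose)[1],
                                     pose[2] - as.numeric(initial_pose)[2],
                                     pose[3] - as.numeric(initial_pose)[3]),
                 history = as.data.frame(hist), ncc = final_ncc,
                 converged = converged, iterations = it, flag = flag),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: pose (%.2f, %.2f, %.2f) nm, NCC %.4f, %s in %d iteration(s)\n",
              x$pose[1], x$pose[2], x$pose[3], x$ncc,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Simulate drifting acquisition with periodic re-alignment
#'
#' The true sample pose drifts (linear rate plus a seeded random walk); the
#' simulated stage re-aligns to the reference at every `interval` frames.
#' Returns the residual pose error per frame (true pose plus accumulated
#' stage correction).
#'
#' @param vol A [brightfield_volume()].
#' @param drift List with `rate` (nm/frame, length 3) and `rw_sd` (random
#'   walk step standard deviation, nm/frame^0.5, length 3).
#' @param n_frames Number of camera frames to simulate.
#' @param interval Frames between re-alignments (2000 by default).
#' @param cfg A [register_config()].
#' @param seed RNG seed for the random walk.
#' @return Data frame with `frame`, `ex`, `ey`, `ez` (nm residuals) and a
#'   `checkpoint` logical column marking re-alignment frames.
#' @export
simulate_stabilization <- function(vol, drift = list(rate = c(0, 0, 0),
                                                     rw_sd = c(0, 0, 0)),
                                   n_frames = 10000, interval = 2000,
                                   cfg = register_config(), seed = NULL) {
  rate <- rep(drift$rate %||% 0, length.out = 3)
  rw <- rep(drift$rw_sd %||% 0, length.out = 3)
  reference <- sample_brightfield(vol, pose3d())
  with_seed(seed, {
    steps <- cbind(rnorm(n_frames, rate[1], rw[1]),
                   rnorm(n_frames, rate[2], rw[2]),
                   rnorm(n_frames, rate[3], rw[3]))
    true_pose <- apply(steps, 2, cumsum)
    corr <- c(0, 0, 0)
    resid <- matrix(NA_real_, n_frames, 3)
    checkpoint <- rep(FALSE, n_frames)
    for (t in seq_len(n_frames)) {
      if (t %% interval == 0) {
        res <- align(vol, reference, initial_pose = true_pose[t, ] + corr, cfg)
        corr <- as.numeric(res$pose) - true_pose[t, ]
        checkpoint[t] <- TRUE
      }
      resid[t, ] <- true_pose[t, ] + corr
    }
    data.frame(frame = seq_len(n_frames), ex = resid[, 1], ey = resid[, 2],
               ez = resid[, 3], checkpoint = checkpoint)
  })
}
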