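#' Structure descriptors for the ground-truth generator
#'
#' Fluorophore layouts emulating common dSTORM targets: lines (microtubule
#' fragments), rings (clathrin-coated pits), Gaussian-free uniform discs
#' (receptor puncta) and a uniform field.  Coordinates are nanometres in the
#' sample plane.
#'
#' For `structure_line` the label density is per micrometre of contour length
#' and each fluorophore is displaced perpendicular to the line by a centred
#' Gaussian with standard deviation `spread_nm` (the antibody-decorated
#' cross-section).  For `structure_ring`, density is per micrometre of
#' circumference and the spread is radial.  `structure_cluster` scatters
#' fluorophores uniformly in a disc.  Either `n` or a density must be given;
#' with a density the realized count is Poisson.
#'
#' @param x1,y1,x2,y2 Line endpoints (nm).
#' @param cx,cy Centre (nm).
#' @param radius_nm Ring or cluster radius (nm).
#' @param spread_nm Gaussian cross-section standard deviation (nm).
#' @param n Exact number of fluorophores (overrides density).
#' @param density_per_um Linear label density (1/um) for lines and rings.
#' @param density_per_um2 Area density (1/um^2) for clusters and uniform
#'   fields.
#' @return A structure descriptor (list with class `structure_spec`).
#' @name structure_specs
NULL

spec_base <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "structure_spec")
}

#' @rdname structure_specs
#' @export
structure_line <- function(x1, y1, x2, y2, spread_nm = 20,
                           n = NULL, density_per_um = 1000) {
  stopifnot(spread_nm >= 0, is.null(n) || n >= 0, density_per_um > 0)
  if ((x1 == x2) && (y1 == y2)) stop("line endpoints must be distinct")
  spec_base("line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, spread_nm = spread_nm,
            n = n, density_per_um = density_per_um)
}

#' @rdname structure_specs
#' @export
structure_ring <- function(cx, cy, radius_nm, spread_nm = 10,
                           n = NULL, density_per_um = 1000) {
  stopifnot(radius_nm > 0, spread_nm >= 0, density_per_um > 0)
  spec_base("ring", cx = cx, cy = cy, radius_nm = radius_nm,
            spread_nm = spread_nm, n = n, density_per_um = density_per_um)
}

#' @rdname structure_specs
#' @export
structure_cluster <- function(cx, cy, radius_nm, n = NULL,
                              density_per_um2 = 500) {
  stopifnot(radius_nm > 0, density_per_um2 > 0)
  spec_base("cluster", cx = cx, cy = cy, radius_nm = radius_nm, n = n,
            density_per_um2 = density_per_um2)
}

#' @rdname structure_specs
#' @export
structure_uniform <- function(density_per_um2 = 1) {
  stopifnot(density_per_um2 > 0)
  spec_base("uniform", density_per_um2 = density_per_um2)
}

#' Sample ground-truth fluorophore positions
#'
#' Realizes a set of structure descriptors as continuous fluorophore
#' positions inside a rectangular field of view.  Structures whose declared
#' geometry (including 4 spread standard deviations) extends outside the
#' field are rejected.
#'
#' @param structures List of [structure_specs] descriptors.
#' @param field_nm Field of view, `c(width, height)` in nm (scalar recycled).
#' @param seed RNG seed; equal seeds give identical position sets.
#' @return A `ground_truth` object: data frame of positions (`x_nm`, `y_nm`,
#'   `structure`, `type`) plus the field size and descriptors as attributes.
#' @examples
#' gt <- make_structures(list(structure_ring(500, 500, 100, spread_nm = 5)),
#'                       field_nm = 1000, seed = 1)
#' range(sqrt((gt$x_nm - 500)^2 + (gt$y_nm - 500)^2))
#' @export
make_structures <- function(structures, field_nm, seed = NULL) {
  if (inherits(structures, "structure_spec")) structures <- list(structures)
  field_nm <- rep(field_nm, length.out = 2)
  stopifnot(all(field_nm > 0))
  inside <- function(x, y) all(x >= 0 & x <= field_nm[1] & y >= 0 & y <= field_nm[2])
  with_seed(seed, {
    parts <- lapply(seq_along(structures), function(s) {
      sp <- structures[[s]]
      stopifnot(inherits(sp, "structure_spec"))
      if (sp$type == "line") {
        len <- sqrt((sp$x2 - sp$x1)^2 + (sp$y2 - sp$y1)^2)
        if (!inside(c(sp$x1, sp$x2), c(sp$y1, sp$y2)))
          stop("line structure extends outside the field")
        n <- sp$n %||% rpois(1, sp$density_per_um * len / 1000)
        t <- runif(n)
        ux <- (sp$x2 - sp$x1) / len; uy <- (sp$y2 - sp$y1) / len
        d <- if (sp$spread_nm > 0) rnorm(n, 0, sp$spread_nm) else numeric(n)
        data.frame(x_nm = sp$x1 + t * (sp$x2 - sp$x1) - uy * d,
                   y_nm = sp$y1 + t * (sp$y2 - sp$y1) + ux * d,
                   structure = s, type = "line")
      } else if (sp$type == "ring") {
        pad <- sp$radius_nm + 4 * sp$spread_nm
        if (!inside(sp$cx + c(-pad, pad), sp$cy + c(-pad, pad)))
          stop("ring structure extends outside the field")
        n <- sp$n %||% rpois(1, sp$density_per_um * 2 * pi * sp$radius_nm / 1000)
        th <- runif(n, 0, 2 * pi)
        r <- sp$radius_nm + if (sp$spread_nm > 0) rnorm(n, 0, sp$spread_nm) else numeric(n)
        data.frame(x_nm = sp$cx + r * cos(th), y_nm = sp$cy + r * sin(th),
                   structure = s, type = "ring")
      } else if (sp$type == "cluster") {
        pad <- sp$radius_nm
        if (!inside(sp$cx + c(-pad, pad), sp$cy + c(-pad, pad)))
          stop("cluster structure extends outside the field")
        area_um2 <- pi * (sp$radius_nm / 1000)^2
        n <- sp$n %||% rpois(1, sp$density_per_um2 * area_um2)
        r <- sp$radius_nm * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
        data.frame(x_nm = sp$cx + r * cos(th), y_nm = sp$cy + r * sin(th),
                   structure = s, type = "cluster")
      } else {
        n <- rpois(1, sp$density_per_um2 * prod(field_nm) / 1e6)
        data.frame(x_nm = runif(n, 0, field_nm[1]),
                   y_nm = runif(n, 0, field_nm[2]),
                   structure = s, type = "uniform")
      }
    })
    gt <- do.call(rbind, parts)
    if (is.null(gt)) gt <- data.frame(x_nm = numeric(), y_nm = numeric(),
                                      structure = integer(), type = character())
    # spread can push individual fluorophores out: clip to the field edge
    keep <- gt$x_nm >= 0 & gt$x_nm <= field_nm[1] &
            gt$y_nm >= 0 & gt$y_nm <= field_nm[2]
    gt <- gt[keep, , drop = FALSE]
    rownames(gt) <- NULL
    attr(gt, "field_nm") <- field_nm
    attr(gt, "structures") <- structures
    class(gt) <- c("ground_truth", "data.frame")
    gt
  })
}

#' Photophysics parameters for the blinking model
#'
#' A discrete-frame two-state Markov chain with geometric bleaching: a dark
#' fluorophore switches on with probability `on_rate` per frame, an on
#' fluorophore switches off with probability `off_rate` per frame, and every
#' on-to-off transition bleaches irreversibly with probability
#' `bleach_prob`.  Photons emitted during an on frame are Poisson about
#' `mean_photons`.  The equilibrium duty cycle (ignoring bleaching) is
#' `on_rate / (on_rate + off_rate)`.
#'
#' @param on_rate,off_rate Per-frame switching probabilities in \[0, 1\].
#' @param bleach_prob Bleaching probability per on->off transition.
#' @param mean_photons Mean photons per on frame (> 0).
#' @param bg_photons Mean background photons per pixel per frame.
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(on_rate = 5e-4, off_rate = 0.5,
                                bleach_prob = 0.1, mean_photons = 1000,
                                bg_photons = 5) {
  stopifnot(on_rate >= 0, on_rate <= 1, off_rate >= 0, off_rate <= 1,
            bleach_prob >= 0, bleach_prob <= 1, mean_photons > 0,
            bg_photons >= 0)
  structure(list(on_rate = on_rate, off_rate = off_rate,
                 bleach_prob = bleach_prob, mean_photons = mean_photons,
                 bg_photons = bg_photons), class = "photophysics_params")
}

#' Simulate stochastic blinking of the ground-truth fluorophores
#'
#' All emitters start dark.  Returns the per-frame emission schedule: which
#' emitters are on in each frame and how many photons each emits.
#'
#' @param gt A [make_structures()] ground truth.
#' @param p A [photophysics_params()].
#' @param n_frames Number of camera frames (>= 1).
#' @param seed RNG seed.
#' @return An `emission_schedule`: data frame with columns `frame` (1-based),
#'   `emitter` (row index into `gt`) and `photons`; attributes carry the
#'   per-emitter bleach frame (NA = never bleached), `n_frames`,
#'   `n_emitters` and the photophysics.
#' @export
simulate_blinking <- function(gt, p, n_frames, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(p, "photophysics_params"),
            n_frames >= 1)
  n <- nrow(gt)
  with_seed(seed, {
    state <- integer(n)  # 0 dark, 1 on, 2 bleached
    bleach_frame <- rep(NA_integer_, n)
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      u <- runif(n)
      turn_on <- state == 0L & u < p$on_rate
      on_now <- state == 1L
      turn_off <- on_now & u < p$off_rate
      state[turn_on] <- 1L
      if (any(turn_off)) {
        bleach <- turn_off & (runif(n) < p$bleach_prob)
        state[turn_off] <- 0L
        state[bleach] <- 2L
        bleach_frame[bleach & is.na(bleach_frame)] <- t
      }
      active <- which(state == 1L)
      if (length(active))
        frames[[t]] <- data.frame(frame = t, emitter = active,
                                  photons = rpois(length(active), p$mean_photons))
    }
    sched <- do.call(rbind, frames)
    if (is.null(sched))
      sched <- data.frame(frame = integer(), emitter = integer(),
                          photons = integer())
    rownames(sched) <- NULL
    attr(sched, "bleach_frame") <- bleach_frame
    attr(sched, "n_frames") <- as.integer(n_frames)
    attr(sched, "n_emitters") <- n
    attr(sched, "photophysics") <- p
    class(sched) <- c("emission_schedule", "data.frame")
    sched
  })
}

#' Thin an emission schedule to emulate incomplete photodestruction
#'
#' Each emitter survives photodestruction independently with probability
#' `fraction`; all emission events of non-surviving emitters are removed.
#' Used to build "after photodestruction" movies with known cross-talk.
#'
#' @param schedule An [simulate_blinking()] emission schedule.
#' @param fraction Survival probability in \[0, 1\].
#' @param seed RNG seed.
#' @return A thinned `emission_schedule`.
#' @export
inject_residuals <- function(schedule, fraction, seed = NULL) {
  stopifnot(inherits(schedule, "emission_schedule"),
            fraction >= 0, fraction <= 1)
  n <- attr(schedule, "n_emitters")
  with_seed(seed, {
    keep <- runif(n) < fraction
    out <- schedule[keep[schedule$emitter], , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("bleach_frame", "n_frames", "n_emitters", "photophysics"))
      attr(out, a) <- attr(schedule, a)
    attr(out, "retained") <- which(keep)
    class(out) <- class(schedule)
    out
  })
}

#' Render an emission schedule into a raw camera movie
#'
#' Expected photons per pixel are the sum over active emitters of a
#' pixel-integrated 2D Gaussian PSF (total intensity = the scheduled photon
#' count) plus a uniform background.  Shot noise is Poisson; the camera then
#' maps photons to ADU as `round(offset + photons / gain)`, clipped to
#' \[0, 65535\].  EMCCD excess noise is not modelled.
#'
#' @param schedule An [simulate_blinking()] emission schedule.
#' @param gt The matching ground truth (emitter indices refer to its rows).
#' @param cam A [camera_model()].
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param bg_photons Mean background photons per pixel; defaults to the
#'   schedule's photophysics value.
#' @param noise If `FALSE`, skip the Poisson draw (expected-value movie).
#' @param seed RNG seed for the shot noise.
#' @return A `frame_stack`: integer array `(width, height, n_frames)` of ADU
#'   values with the camera and PSF width attached as attributes.
#' @export
render_frame_stack <- function(schedule, gt, cam, psf_sigma_px = 1.0,
                               bg_photons = NULL, noise = TRUE, seed = NULL) {
  stopifnot(inherits(schedule, "emission_schedule"),
            inherits(gt, "ground_truth"), inherits(cam, "camera_model"),
            psf_sigma_px > 0)
  bg <- bg_photons %||% attr(schedule, "photophysics")$bg_photons %||% 0
  nx <- cam$width; ny <- cam$height
  n_frames <- attr(schedule, "n_frames")
  x_px <- gt$x_nm / cam$pixel_nm
  y_px <- gt$y_nm / cam$pixel_nm
  idx <- split(seq_len(nrow(schedule)), factor(schedule$frame, levels = seq_len(n_frames)))
  stack <- array(0L, dim = c(nx, ny, n_frames))
  npx <- nx * ny
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      rows <- idx[[t]]
      em <- schedule$emitter[rows]
      lambda <- cpp_expected_frame(nx, ny, x_px[em], y_px[em],
                                   as.numeric(schedule$photons[rows]),
                                   bg, psf_sigma_px)
      ph <- if (noise) rpois(npx, lambda) else lambda
      adu <- round(cam$offset + ph / cam$gain)
      stack[, , t] <- as.integer(pmin(65535, pmax(0, adu)))
    }
  })
  structure(stack, cam = cam, psf_sigma_px = psf_sigma_px,
            class = c("frame_stack", "array"))
}
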