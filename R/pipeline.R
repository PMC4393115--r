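#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of the demonstration pipeline.  The default scale
#' is reduced from a full acquisition (10,000-20,000 frames at 256 x 256)
#' to 2000 frames at 128 x 128 so a complete run fits on one desktop CPU;
#' full scale is reachable by overriding `camera` and `n_frames`.
#' Serializes losslessly to JSON via [write_config()]/[read_config()].
#'
#' @param camera A [camera_model()].
#' @param photophysics A [photophysics_params()].
#' @param psf_sigma_px PSF standard deviation (pixels).
#' @param thresholds A [filter_thresholds()].
#' @param registration A [register_config()].
#' @param sr_pixel_nm SR rendering pixel (nm).
#' @param n_frames Frames per imaging round.
#' @param n_lines Number of linear structures imaged in both rounds.
#' @param line_density_per_um Fluorophore density along each line (1/um).
#' @param line_spread_nm Structural cross-section spread (nm).
#' @param residual_fraction Emitter survival fraction after photodestruction.
#' @param pose_error_nm Pose perturbation injected between rounds (nm).
#' @param candidate_threshold Candidate detection threshold.
#' @param overlay_indices Two color indices for the composite.
#' @param write_stacks Also write the raw ADU movies (large).
#' @param seed Base seed; every stage derives its own stream from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(camera = camera_model(width = 128, height = 128),
                       photophysics = photophysics_params(),
                       psf_sigma_px = 1.0,
                       thresholds = filter_thresholds(),
                       registration = register_config(),
                       sr_pixel_nm = 10,
                       n_frames = 2000,
                       n_lines = 6,
                       line_density_per_um = 300,
                       line_spread_nm = 20,
                       residual_fraction = 0.002,
                       pose_error_nm = c(120, -80, 150),
                       candidate_threshold = 4,
                       overlay_indices = list(c(1, 0, 1), c(0, 1, 0)),
                       write_stacks = FALSE,
                       seed = 0) {
  structure(list(camera = camera, photophysics = photophysics,
                 psf_sigma_px = psf_sigma_px, thresholds = thresholds,
                 registration = registration, sr_pixel_nm = sr_pixel_nm,
                 n_frames = n_frames, n_lines = n_lines,
                 line_density_per_um = line_density_per_um,
                 line_spread_nm = line_spread_nm,
                 residual_fraction = residual_fraction,
                 pose_error_nm = pose_error_nm,
                 candidate_threshold = candidate_threshold,
                 overlay_indices = overlay_indices,
                 write_stacks = write_stacks, seed = seed),
            class = "run_config")
}

#' Write/read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    camera = do.call(camera_model, p$camera[c("pixel_um", "width", "height",
                                              "offset", "gain", "exposure_ms")]),
    photophysics = do.call(photophysics_params, p$photophysics),
    psf_sigma_px = p$psf_sigma_px,
    thresholds = do.call(filter_thresholds, p$thresholds),
    registration = do.call(register_config,
                           p$registration[c("half_range_nm", "step_nm", "n_fit",
                                            "tol_xy_nm", "tol_z_nm", "max_iter")]),
    sr_pixel_nm = p$sr_pixel_nm, n_frames = p$n_frames, n_lines = p$n_lines,
    line_density_per_um = p$line_density_per_um,
    line_spread_nm = p$line_spread_nm,
    residual_fraction = p$residual_fraction,
    pose_error_nm = p$pose_error_nm,
    candidate_threshold = p$candidate_threshold,
    overlay_indices = if (is.matrix(p$overlay_indices))
      lapply(seq_len(nrow(p$overlay_indices)), function(i) p$overlay_indices[i, ])
      else p$overlay_indices,
    write_stacks = p$write_stacks, seed = p$seed)
}

#' Append-only session log
#'
#' @param path Optional file the log is mirrored to.
#' @return A `session_log` environment with `$add(msg)` and `$events`.
#' @export
session_log <- function(path = NULL) {
  env <- new.env()
  env$events <- character()
  env$path <- path
  env$add <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    env$events <- c(env$events, line)
    if (!is.null(env$path)) cat(line, "\n", file = env$path, append = TRUE, sep = "")
    invisible(line)
  }
  class(env) <- "session_log"
  env
}

# Line structures used by the two-round demo: parallel-ish diagonal lines
# spread over the field with a margin keeping the 9x9 ROI fully inside.
demo_line_specs <- function(cam, n_lines, density_per_um, spread_nm) {
  w <- cam$width * cam$pixel_nm; h <- cam$height * cam$pixel_nm
  mar <- 12 * cam$pixel_nm
  lapply(seq_len(n_lines), function(k) {
    fy <- k / (n_lines + 1)
    structure_line(x1 = mar, y1 = h * fy - 0.05 * h,
                   x2 = w - mar, y2 = h * fy + 0.05 * h,
                   spread_nm = spread_nm, density_per_um = density_per_um)
  })
}

#' Two-round overlay-precision experiment (alpha/beta-tubulin emulation)
#'
#' Full simulated realization of the sequential imaging precision
#' measurement: a set of linear structures is imaged twice (as when labeling
#' alpha- then beta-tubulin on the same microtubules); between rounds a
#' random 3D pose error is injected and corrected by iterative brightfield
#' registration at the 5/5/10 nm tolerances, so the second round carries
#' only the uncorrected registration residual.  Both movies are localized
#' with the Poisson-MLE chain and each segment's overlay error is measured
#' by the rotation + perpendicular Gaussian-profile procedure.
#'
#' @param seed Replicate seed (controls structures, blinking, shot noise,
#'   texture and pose error).
#' @param n_frames Frames per round.
#' @param n_segments Number of linear structures/segments.
#' @param density_per_um Fluorophore density along each line (1/um).
#' @param spread_nm Structural cross-section spread (nm).
#' @param mean_photons Mean photons per on frame.
#' @param pose_error_xy_nm,pose_error_z_nm Half-ranges of the injected
#'   uniform pose error (nm).
#' @param cam A [camera_model()] (the reduced 128 x 128 crop by default).
#' @return List: `shifts_nm` (signed local shift per segment),
#'   `registration` result, `global` shift estimate, and per-round accepted
#'   localization counts.
#' @export
overlay_precision_experiment <- function(seed, n_frames = 1500,
                                         n_segments = 10,
                                         density_per_um = 180,
                                         spread_nm = 20,
                                         mean_photons = 500,
                                         pose_error_xy_nm = 250,
                                         pose_error_z_nm = 300,
                                         cam = camera_model(width = 128,
                                                            height = 128)) {
  phys <- photophysics_params(on_rate = 1e-3, off_rate = 0.5,
                              bleach_prob = 0.1,
                              mean_photons = mean_photons, bg_photons = 5)
  w <- cam$width * cam$pixel_nm; h <- cam$height * cam$pixel_nm
  mar <- 12 * cam$pixel_nm
  specs <- lapply(seq_len(n_segments), function(k) {
    fy <- k / (n_segments + 1)
    structure_line(mar, h * fy - 0.03 * h, w - mar, h * fy + 0.03 * h,
                   spread_nm = spread_nm, density_per_um = density_per_um)
  })
  gt <- make_structures(specs, field_nm = c(w, h), seed = seed)
  run_round <- function(gtr, s) {
    sch <- simulate_blinking(gtr, phys, n_frames, seed = s)
    st <- render_frame_stack(sch, gtr, cam, 1.0, seed = s + 1)
    localize_stack(st, cam, 1.0)
  }
  tabA <- run_round(gt, seed + 100)
  vol <- brightfield_volume(pixel_nm = cam$pixel_nm, seed = seed + 7)
  reference <- sample_brightfield(vol, pose3d())
  p0 <- with_seed(seed + 8,
                  c(runif(2, -pose_error_xy_nm, pose_error_xy_nm),
                    runif(1, -pose_error_z_nm, pose_error_z_nm)))
  reg <- align(vol, reference, initial_pose = p0)
  gtB <- gt
  gtB$x_nm <- gtB$x_nm + reg$pose[1]
  gtB$y_nm <- gtB$y_nm + reg$pose[2]
  tabB <- run_round(gtB, seed + 200)
  segs <- lapply(specs, function(s) segment_spec(s$x1, s$y1, s$x2, s$y2))
  rep <- shift_report(tabA, tabB, segs, pixel_nm = 10, field_nm = c(w, h))
  list(shifts_nm = rep$segments$shift_nm, registration = reg,
       global = rep$global, injected_pose = p0,
       n_accepted = c(A = sum(tabA$accepted), B = sum(tabB$accepted)))
}

#' Simulate, localize and quantify a full two-round experiment
#'
#' End-to-end realization of sequential imaging on synthetic data: image a
#' set of linear structures (round A), photodestroy leaving a residual
#' fraction and re-image for the cross-talk estimate, perturb the sample
#' pose and correct it by brightfield registration, then re-image the same
#' structures (round B) and quantify the overlay by global and per-segment
#' local shifts.  All outputs (tables, SR images, overlay, reports, resolved
#' config, log) are written under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return List with the localization tables, registration result,
#'   crosstalk and shift reports, SR images and overlay, and the log.
#' @export
demo_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cam <- config$camera
  log <- session_log(if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "log.txt")
  })
  seed <- config$seed
  log$add(sprintf("demo_pipeline start (seed %d, %d frames, %dx%d px)",
                  seed, config$n_frames, cam$width, cam$height))

  specs <- demo_line_specs(cam, config$n_lines, config$line_density_per_um,
                           config$line_spread_nm)
  gt <- make_structures(specs, field_nm = c(cam$width, cam$height) * cam$pixel_nm,
                        seed = seed + 1)
  log$add(sprintf("ground truth: %d fluorophores in %d lines", nrow(gt),
                  config$n_lines))

  run_round <- function(gt_round, round_seed, label) {
    sched <- simulate_blinking(gt_round, config$photophysics, config$n_frames,
                               seed = round_seed)
    stack <- render_frame_stack(sched, gt_round, cam, config$psf_sigma_px,
                                seed = round_seed + 1)
    tab <- localize_stack(stack, cam, config$psf_sigma_px, config$thresholds,
                          threshold = config$candidate_threshold)
    log$add(sprintf("%s: %d emission events, %d localizations, %d accepted",
                    label, nrow(sched), nrow(tab), sum(tab$accepted)))
    list(sched = sched, stack = stack, tab = tab)
  }

  ## round A
  a <- run_round(gt, seed + 10, "round A")

  ## photodestruction residual re-imaging for cross-talk
  resid_sched <- inject_residuals(a$sched, config$residual_fraction,
                                  seed = seed + 20)
  resid_stack <- render_frame_stack(resid_sched, gt, cam, config$psf_sigma_px,
                                    bg_photons = config$photophysics$bg_photons,
                                    seed = seed + 21)
  resid_tab <- localize_stack(resid_stack, cam, config$psf_sigma_px,
                              config$thresholds,
                              threshold = config$candidate_threshold)
  ct <- crosstalk(a$tab, resid_tab, min_before = 20)
  log$add(sprintf("cross-talk: mean %.3f%% over %d subregions", ct$mean_pct,
                  ct$n_regions))

  ## registration of the injected pose error (brightfield runs at its native
  ## 256 x 256 frame regardless of the SMLM crop)
  vol <- brightfield_volume(pixel_nm = cam$pixel_nm, seed = seed + 30)
  reference <- sample_brightfield(vol, pose3d())
  reg <- align(vol, reference, initial_pose = config$pose_error_nm,
               cfg = config$registration)
  log$add(sprintf("registration: residual (%.2f, %.2f, %.2f) nm, NCC %.3f, %s",
                  reg$pose[1], reg$pose[2], reg$pose[3], reg$ncc,
                  if (reg$converged) "converged" else "NOT converged"))

  ## round B: same structures, displaced by the uncorrected registration
  ## residual in the imaging plane
  gt_b <- gt
  gt_b$x_nm <- gt_b$x_nm + reg$pose[1]
  gt_b$y_nm <- gt_b$y_nm + reg$pose[2]
  b <- run_round(gt_b, seed + 40, "round B")

  ## reconstruction, overlay, shift quantification
  field <- c(cam$width, cam$height) * cam$pixel_nm
  imgA <- render_sr(a$tab, pixel_nm = config$sr_pixel_nm, field_nm = field)
  imgB <- render_sr(b$tab, pixel_nm = config$sr_pixel_nm, field_nm = field)
  ov <- overlay(list(imgA, imgB), config$overlay_indices)
  segs <- lapply(specs, function(s)
    segment_spec(s$x1, s$y1, s$x2, s$y2, min_locs = 50))
  rep <- shift_report(a$tab, b$tab, segs, pixel_nm = config$sr_pixel_nm,
                      field_nm = field)
  log$add(sprintf("shift: global (%.2f, %.2f) nm, median |local| %.2f nm",
                  rep$global$dx, rep$global$dy,
                  median(abs(rep$segments$shift_nm))))

  if (!is.null(out_dir)) {
    write_config(config, file.path(out_dir, "config.json"))
    write_localizations(a$tab, file.path(out_dir, "locs_roundA.csv"))
    write_localizations(resid_tab, file.path(out_dir, "locs_residual.csv"))
    write_localizations(b$tab, file.path(out_dir, "locs_roundB.csv"))
    data.table::fwrite(ct$regions, file.path(out_dir, "crosstalk_regions.csv"))
    data.table::fwrite(rep$segments, file.path(out_dir, "local_shifts.csv"))
    write_tiff_stack(unclass(imgA), file.path(out_dir, "sr_roundA.tif"),
                     type = "float32")
    write_tiff_stack(unclass(imgB), file.path(out_dir, "sr_roundB.tif"),
                     type = "float32")
    write_tiff_stack(aperm(unclass(ov), c(1, 2, 3)),
                     file.path(out_dir, "overlay_rgb.tif"), type = "float32")
    if (isTRUE(config$write_stacks)) {
      write_tiff_stack(a$stack, file.path(out_dir, "stack_roundA.tif"))
      write_tiff_stack(resid_stack, file.path(out_dir, "stack_residual.tif"))
      write_tiff_stack(b$stack, file.path(out_dir, "stack_roundB.tif"))
    }
    log$add(sprintf("outputs written to %s", normalizePath(out_dir)))
  }

  list(ground_truth = gt, roundA = a$tab, residual = resid_tab,
       roundB = b$tab, crosstalk = ct, registration = reg,
       shift_report = rep, sr = list(A = imgA, B = imgB), overlay = ov,
       log = log$events)
}
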