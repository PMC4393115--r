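#' Localization filter thresholds
#'
#' Acceptance thresholds applied to fitted emitters: a maximum background
#' photon count per pixel (50-100 is the usual working range; the default
#' takes the upper end), a minimum total photon count per frame per emitter
#' of 250, and a minimum goodness-of-fit p-value of 0.01.
#'
#' @param max_bg Maximum background photons per pixel.
#' @param min_photons Minimum total photons per localization.
#' @param min_pvalue Minimum goodness-of-fit p-value.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_bg = 100, min_photons = 250,
                              min_pvalue = 0.01) {
  stopifnot(max_bg > 0, min_photons > 0, min_pvalue > 0)
  structure(list(max_bg = max_bg, min_photons = min_photons,
                 min_pvalue = min_pvalue), class = "filter_thresholds")
}

#' Find candidate emitters in a photon-count image
#'
#' Two smoothing passes (separable boxcar filters of radius `r_small` and
#' `r_large`) reduce the Poisson noise; their difference is a band-pass image
#' in which strict local maxima above `threshold` become fitting-region
#' centres.  Maxima closer together than one ROI half-width are merged
#' (brighter wins) and maxima too close to the border for a full ROI are
#' dropped.
#'
#' @param img Photon-count matrix (x = first index, 0-based coordinates
#'   returned).
#' @param threshold Detection threshold in smoothed-photon units.
#' @param roi_size Fitting-region size in pixels (odd).
#' @param r_small,r_large Boxcar smoothing radii.
#' @return Data frame with 0-based pixel coordinates `ix`, `iy` and the
#'   band-pass `value` at each candidate.
#' @export
find_candidates <- function(img, threshold = 4, roi_size = 9,
                            r_small = 2, r_large = 4) {
  stopifnot(is.matrix(img), all(img >= 0), roi_size %% 2 == 1)
  half <- (roi_size - 1L) %/% 2L
  m <- cpp_find_candidates(img, threshold, as.integer(r_small),
                           as.integer(r_large), 2L, half, half)
  data.frame(ix = as.integer(m[, 1]), iy = as.integer(m[, 2]),
             value = m[, 3])
}

#' Detection threshold from the smoothed-background noise level
#'
#' Standard deviation of the small-radius boxcar smoothing of a pure Poisson
#' background, times `n_sigma`; the usual operating point for
#' [find_candidates()] is 4 sigma.
#'
#' @param bg_photons Mean background photons per pixel.
#' @param r_small Small boxcar radius (as in [find_candidates()]).
#' @param n_sigma Threshold multiple.
#' @return Threshold in smoothed-photon units.
#' @export
candidate_threshold_sigma <- function(bg_photons, r_small = 2, n_sigma = 4) {
  n_sigma * sqrt(bg_photons / (2 * r_small + 1)^2)
}

#' Fit a single fitting region by Poisson maximum likelihood
#'
#' Maximizes the Poisson log-likelihood of the pixel-integrated Gaussian PSF
#' model `mu = I * dEx * dEy + bg` over (x, y, I, bg) with per-parameter
#' Newton-Raphson updates (20 iterations maximum; convergence at 1e-4 px /
#' 1e-2 photons).  The PSF width is a fixed, known constant, not a fitted
#' parameter.  Positions are in ROI-local pixel coordinates (pixel i spans
#' `[i, i+1)`).
#'
#' @param roi Square photon-count matrix (default geometry 9 x 9).
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param max_iter,tol_xy,tol_photon Newton-Raphson controls.
#' @return A `fit_result` list: `x`, `y`, `I`, `bg`, `logL`, `iterations`,
#'   `converged`, and the ROI geometry.
#' @export
fit_roi <- function(roi, psf_sigma_px = 1.0, max_iter = 20,
                    tol_xy = 1e-4, tol_photon = 1e-2) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi), all(roi >= 0),
            psf_sigma_px > 0)
  n <- nrow(roi)
  m <- cpp_fit_rois(matrix(as.numeric(roi), ncol = 1), psf_sigma_px, n,
                    as.integer(max_iter), tol_xy, tol_photon)
  structure(list(x = unname(m[1, "x"]), y = unname(m[1, "y"]),
                 I = unname(m[1, "I"]), bg = unname(m[1, "bg"]),
                 logL = unname(m[1, "logL"]),
                 iterations = unname(m[1, "iterations"]),
                 converged = unname(m[1, "converged"]) == 1, n = n,
                 psf_sigma_px = psf_sigma_px),
            class = "fit_result")
}

#' Cramer-Rao lower bound precisions for a fit
#'
#' Builds the 4 x 4 Fisher information of the Poisson ROI model,
#' `F_ab = sum_k (1/mu_k) (dmu_k/da) (dmu_k/db)`, at the fitted parameters
#' and returns the square roots of the diagonal of its inverse: the best
#' achievable standard deviations of x, y (pixels), I and bg (photons).
#'
#' @param fit A [fit_roi()] result (or any list with `x`, `y`, `I`, `bg`).
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param n ROI side length in pixels.
#' @return Named list `sd_x`, `sd_y`, `sd_I`, `sd_bg`, `singular`.
#' @export
crlb <- function(fit, psf_sigma_px = fit$psf_sigma_px %||% 1.0,
                 n = fit$n %||% 9) {
  stopifnot(fit$I > 0)
  m <- cpp_crlb(matrix(c(fit$x, fit$y, fit$I, fit$bg), nrow = 1),
                psf_sigma_px, as.integer(n))
  list(sd_x = m[1, "sd_x"], sd_y = m[1, "sd_y"], sd_I = m[1, "sd_I"],
       sd_bg = m[1, "sd_bg"], singular = m[1, "singular"] == 1)
}

#' Goodness-of-fit p-value for a fitted region
#'
#' Poisson deviance (likelihood-ratio) statistic
#' `2 * sum(mu - d + d * log(d / mu))` (zero-count pixels contribute `mu`),
#' rescaled by its exact null expectation per pixel (the chi-squared
#' approximation overshoots for low-count Poisson pixels) and referred to a
#' chi-squared distribution with `n^2 - 4` degrees of freedom; returns the
#' upper-tail probability.  Small p flags regions the single-emitter model
#' cannot explain (e.g. overlapping emitters).
#'
#' @param roi Photon-count matrix the fit was computed from.
#' @param fit The corresponding [fit_roi()] result.
#' @return p-value in \[0, 1\].
#' @export
gof_pvalue <- function(roi, fit) {
  n <- nrow(roi)
  mu <- cpp_roi_mu(matrix(c(fit$x, fit$y, fit$I, fit$bg), nrow = 1),
                   fit$psf_sigma_px %||% 1.0, n)
  deviance_pvalue(matrix(as.numeric(roi), ncol = 1), mu, df = n * n - 4)
}

# Deviance p-values for a batch of ROIs (pixels x N matrices).  The statistic
# is scaled by its estimated null expectation: E[dev_k] departs from 1 for
# small Poisson means (~1 + 1/(6 mu) for moderate mu, computed exactly on a
# cached grid below).
deviance_pvalue <- function(rois, mus, df) {
  term <- ifelse(rois > 0, mus - rois + rois * log(rois / mus), mus)
  stat <- 2 * colSums(term)
  scale <- colMeans(matrix(dev_expectation(mus), nrow = nrow(mus)))
  pchisq(stat / scale, df = df, lower.tail = FALSE)
}

dev_cache <- new.env(parent = emptyenv())

# exact E[2(mu - d + d log(d/mu))] for Poisson d, interpolated on a log grid
dev_expectation <- function(mu) {
  if (is.null(dev_cache$grid_E)) {
    g <- exp(seq(log(1e-4), log(3000), length.out = 400))
    dev_cache$grid_mu <- g
    dev_cache$grid_E <- vapply(g, function(m) {
      kmax <- max(20, ceiling(m + 12 * sqrt(m)))
      k <- 0:kmax
      p <- stats::dpois(k, m)
      sum(p * 2 * (m - k + ifelse(k > 0, k * log(k / m), 0)))
    }, numeric(1))
  }
  E <- approx(log(dev_cache$grid_mu), dev_cache$grid_E,
              xout = pmin(pmax(log(mu), log(1e-4)), log(3000)),
              rule = 2)$y
  big <- mu > 3000
  E[big] <- 1 + 1 / (6 * mu[big])
  E
}

#' Apply acceptance thresholds to a localization table
#'
#' A record is accepted iff the fit converged, `bg <= max_bg`,
#' `photons >= min_photons` and `pvalue >= min_pvalue`.  The three threshold
#' tests commute and the operation is idempotent.
#'
#' @param table Localization data frame (columns `photons`, `bg`, `pvalue`,
#'   `converged`).
#' @param thresholds A [filter_thresholds()].
#' @return The table with its `accepted` column (re)computed.
#' @export
filter_localizations <- function(table, thresholds = filter_thresholds()) {
  need <- c("photons", "bg", "pvalue", "converged")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  table$accepted <- table$converged &
    table$bg <= thresholds$max_bg &
    table$photons >= thresholds$min_photons &
    table$pvalue >= thresholds$min_pvalue
  table
}

#' Area of the fitting region at the sample plane
#'
#' @param cam A [camera_model()].
#' @param roi_size Fitting-region side in pixels.
#' @return Area in um^2 (e.g. 0.92 um^2 for 9 px at 0.1067 um).
#' @export
fitting_region_area_um2 <- function(cam = camera_model(), roi_size = 9) {
  (roi_size * cam$pixel_um)^2
}

#' Localize an entire movie
#'
#' Runs the full per-frame chain: ADU -> photons, candidate detection, 9 x 9
#' ROI maximum-likelihood fitting, CRLB precisions, goodness-of-fit p-value
#' and threshold filtering.  ROIs clipped by the frame border are discarded.
#' Positions are reported in nm (continuous pixel coordinate times pixel
#' size).
#'
#' @param stack `frame_stack` or plain 3D ADU array `(nx, ny, n_frames)`.
#' @param cam A [camera_model()]; defaults to the stack's own.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param thresholds A [filter_thresholds()].
#' @param threshold Candidate detection threshold (smoothed photons).
#' @param roi_size Fitting-region side in pixels (odd).
#' @param verbose Print per-stack summary counts.
#' @return A localization table (`data.frame`, class `localization_table`)
#'   with columns `frame`, `x_nm`, `y_nm`, `x_px`, `y_px`, `photons`, `bg`,
#'   `sigma_x_nm`, `sigma_y_nm`, `pvalue`, `converged`, `accepted`.
#' @export
localize_stack <- function(stack, cam = attr(stack, "cam"),
                           psf_sigma_px = attr(stack, "psf_sigma_px") %||% 1.0,
                           thresholds = filter_thresholds(),
                           threshold = 4, roi_size = 9, verbose = FALSE) {
  stopifnot(length(dim(stack)) == 3, inherits(cam, "camera_model"))
  n_frames <- dim(stack)[3]
  half <- (roi_size - 1L) %/% 2L
  rois <- list(); meta <- list(); nc <- 0L
  for (t in seq_len(n_frames)) {
    ph <- adu_to_photons(stack[, , t], cam)
    cand <- find_candidates(ph, threshold = threshold, roi_size = roi_size)
    if (!nrow(cand)) next
    for (k in seq_len(nrow(cand))) {
      ox <- cand$ix[k] - half; oy <- cand$iy[k] - half
      nc <- nc + 1L
      rois[[nc]] <- as.numeric(ph[(ox + 1):(ox + roi_size),
                                  (oy + 1):(oy + roi_size)])
      meta[[nc]] <- c(t, ox, oy)
    }
  }
  if (nc == 0L) {
    return(empty_localization_table())
  }
  roimat <- matrix(unlist(rois), nrow = roi_size^2)
  metamat <- do.call(rbind, meta)
  fits <- cpp_fit_rois(roimat, psf_sigma_px, as.integer(roi_size), 20L, 1e-4, 1e-2)
  cr <- cpp_crlb(fits[, c("x", "y", "I", "bg"), drop = FALSE], psf_sigma_px,
                 as.integer(roi_size))
  mu <- cpp_roi_mu(fits[, c("x", "y", "I", "bg"), drop = FALSE], psf_sigma_px,
                   as.integer(roi_size))
  pval <- deviance_pvalue(roimat, mu, df = roi_size^2 - 4)
  x_px <- metamat[, 2] + fits[, "x"]
  y_px <- metamat[, 3] + fits[, "y"]
  tab <- data.frame(
    frame = as.integer(metamat[, 1]),
    x_nm = x_px * cam$pixel_nm, y_nm = y_px * cam$pixel_nm,
    x_px = x_px, y_px = y_px,
    photons = fits[, "I"], bg = fits[, "bg"],
    sigma_x_nm = cr[, "sd_x"] * cam$pixel_nm,
    sigma_y_nm = cr[, "sd_y"] * cam$pixel_nm,
    pvalue = pval,
    converged = fits[, "converged"] == 1 & cr[, "singular"] == 0)
  tab <- filter_localizations(tab, thresholds)
  if (verbose)
    message(sprintf("localize_stack: %d frames, %d candidates, %d accepted",
                    n_frames, nc, sum(tab$accepted)))
  class(tab) <- c("localization_table", "data.frame")
  tab
}

empty_localization_table <- function() {
  tab <- data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                    x_px = numeric(), y_px = numeric(), photons = numeric(),
                    bg = numeric(), sigma_x_nm = numeric(),
                    sigma_y_nm = numeric(), pvalue = numeric(),
                    converged = logical(), accepted = logical())
  class(tab) <- c("localization_table", "data.frame")
  tab
}
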