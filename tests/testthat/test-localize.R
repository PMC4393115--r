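test_that("adu_to_photons applies offset, gain and clamping", {
  cam <- camera_model(offset = 100, gain = 0.45)
  expect_equal(adu_to_photons(matrix(300, 1, 1), cam)[1, 1], 90)
  expect_equal(adu_to_photons(matrix(100, 1, 1), cam)[1, 1], 0)
  expect_equal(adu_to_photons(matrix(90, 1, 1), cam)[1, 1], 0)  # clamped
  m <- matrix(c(100, 102, 98, 300), 2, 2)
  expect_true(is.matrix(adu_to_photons(m, cam)))
})

test_that("find_candidates detects emitters and controls false positives", {
  img <- seqsmlm:::cpp_expected_frame(64L, 64L, 30.5, 20.5, 2000, 0, 1.0)
  cand <- find_candidates(img, threshold = 4)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$ix, cand$iy), c(30, 20))

  # two emitters 10 px apart resolve into two candidates
  img2 <- seqsmlm:::cpp_expected_frame(64L, 64L, c(30.5, 40.5), c(20.5, 20.5),
                                       c(1000, 1000), 2, 1.0)
  expect_equal(nrow(find_candidates(img2, threshold = 4)), 2)

  # Monte-Carlo false-positive oracle: pure Poisson background at bg = 5,
  # threshold 4 x the smoothed-background sigma, < 0.1 candidates/frame
  bg <- 5
  thr <- candidate_threshold_sigma(bg)
  set.seed(41)
  fp <- replicate(1000, nrow(find_candidates(matrix(rpois(64 * 64, bg),
                                                    64, 64),
                                             threshold = thr)))
  expect_lt(mean(fp) * (128 / 64)^2, 0.4)  # scaled to the default frame
  expect_lt(mean(fp), 0.1)
})

test_that("fit_roi inverts its own model and handles degenerate input", {
  mu <- roi_model(4.0, 4.0, 1000, 2)
  f <- fit_roi(mu, 1.0)
  expect_true(f$converged)
  expect_lt(abs(f$x - 4.0), 1e-3)
  expect_lt(abs(f$y - 4.0), 1e-3)
  expect_lt(abs(f$I - 1000) / 1000, 1e-3)
  expect_lt(abs(f$bg - 2) / 2, 1e-2)

  # off-centre, different parameters
  f2 <- fit_roi(roi_model(3.2, 5.7, 600, 8), 1.0)
  expect_lt(max(abs(c(f2$x - 3.2, f2$y - 5.7))), 1e-3)

  # uniform ROI: I ~ 0, bg ~ the mean
  u <- fit_roi(matrix(7, 9, 9), 1.0)
  expect_lt(u$I / (81 * 7), 0.05)
  expect_lt(abs(u$bg - 7) / 7, 0.05)

  # all-zero ROI: degenerate zero-intensity fit, not an error
  z <- fit_roi(matrix(0, 9, 9), 1.0)
  expect_equal(z$I, 0)
})

test_that("crlb matches the high-photon closed form and finite differences", {
  # bg -> 0, large I: sd_x ~ sigma_psf / sqrt(I) (pixel-integration widens
  # the effective sigma slightly; 5% band)
  f <- list(x = 4.5, y = 4.5, I = 1e5, bg = 1e-9)
  cr <- crlb(f, psf_sigma_px = 1.0, n = 9)
  expect_lt(abs(cr$sd_x - 1 / sqrt(1e5)) / (1 / sqrt(1e5)), 0.05)

  # doubling the background strictly increases sd_x
  cr1 <- crlb(list(x = 4.5, y = 4.5, I = 1000, bg = 5))
  cr2 <- crlb(list(x = 4.5, y = 4.5, I = 1000, bg = 10))
  expect_gt(cr2$sd_x, cr1$sd_x)

  # finite-difference Fisher information oracle
  theta <- c(x = 4.3, y = 4.8, I = 900, bg = 6)
  eps <- c(1e-5, 1e-5, 1e-2, 1e-4)
  mu_at <- function(th) as.numeric(roi_model(th[1], th[2], th[3], th[4]))
  mu0 <- mu_at(theta)
  J <- sapply(1:4, function(a) {
    tp <- theta; tp[a] <- tp[a] + eps[a]
    tm <- theta; tm[a] <- tm[a] - eps[a]
    (mu_at(tp) - mu_at(tm)) / (2 * eps[a])
  })
  Fnum <- t(J) %*% (J / mu0)
  sd_num <- sqrt(diag(solve(Fnum)))
  cr3 <- crlb(as.list(theta))
  expect_lt(abs(cr3$sd_x - sd_num[1]) / sd_num[1], 1e-3)
  expect_lt(abs(cr3$sd_y - sd_num[2]) / sd_num[2], 1e-3)
  expect_lt(abs(cr3$sd_I - sd_num[3]) / sd_num[3], 1e-3)
})

test_that("gof_pvalue is exact on perfect fits and rejects double emitters", {
  mu <- roi_model(4.0, 4.0, 1000, 2)
  f <- fit_roi(mu, 1.0)
  expect_equal(gof_pvalue(mu, f), 1)  # d == mu: statistic 0

  # unmodeled second emitter of equal brightness 3 px away: p < 0.01 in >90%
  mu2 <- roi_model(4.5, 4.5, 1000, 5) + roi_model(7.5, 4.5, 1000, 0)
  set.seed(5)
  rej <- replicate(200, {
    roi <- matrix(rpois(81, as.numeric(mu2)), 9, 9)
    gof_pvalue(roi, fit_roi(roi, 1.0)) < 0.01
  })
  expect_gt(mean(rej), 0.9)
})

test_that("filter_localizations applies the acceptance thresholds", {
  tab <- data.frame(photons = c(200, 300, 400, 400, 400),
                    bg = c(50, 50, 50, 120, 50),
                    pvalue = c(0.5, 0.5, 0.5, 0.5, 0.005),
                    converged = TRUE)
  out <- filter_localizations(tab, filter_thresholds(max_bg = 100,
                                                     min_photons = 250,
                                                     min_pvalue = 0.01))
  expect_identical(out$accepted, c(FALSE, TRUE, TRUE, FALSE, FALSE))

  # idempotent and order-independent across thresholds
  expect_identical(filter_localizations(out, filter_thresholds()), out)
  perm <- out[sample(nrow(out)), ]
  expect_identical(filter_localizations(perm, filter_thresholds())$accepted,
                   perm$accepted)

  # non-convergence always rejects
  tab$converged <- FALSE
  expect_false(any(filter_localizations(tab, filter_thresholds())$accepted))
  expect_error(filter_localizations(data.frame(photons = 1), filter_thresholds()),
               "bg")
})

test_that("fitting-region geometry matches the camera", {
  expect_equal(fitting_region_area_um2(camera_model(), 9), (9 * 0.1067)^2)
  expect_equal(round(fitting_region_area_um2(), 2), 0.92)
})

test_that("localize_stack recovers isolated emitters near the truth", {
  cam <- test_camera(64)
  set.seed(21)
  gt <- make_structures(structure_uniform(density_per_um2 = 12),
                        field_nm = 64 * 106.7, seed = 21)
  phys <- photophysics_params(on_rate = 0.004, off_rate = 0.6,
                              bleach_prob = 0, mean_photons = 1500,
                              bg_photons = 5)
  sched <- simulate_blinking(gt, phys, 300, seed = 22)
  stack <- render_frame_stack(sched, gt, cam, 1.0, seed = 23)
  tab <- localize_stack(stack, cam, 1.0)
  acc <- tab[tab$accepted, ]
  expect_gt(nrow(acc), 100)

  # match accepted localizations to their true emitter: >= 90% of isolated
  # >= 250-photon events within 3 combined sigma of the truth
  sched$x_nm <- gt$x_nm[sched$emitter]
  sched$y_nm <- gt$y_nm[sched$emitter]
  ok <- 0; total <- 0
  for (i in seq_len(nrow(acc))) {
    ev <- sched[sched$frame == acc$frame[i], ]
    d2 <- (ev$x_nm - acc$x_nm[i])^2 + (ev$y_nm - acc$y_nm[i])^2
    j <- which.min(d2)
    if (ev$photons[j] >= 250) {
      total <- total + 1
      tol <- 3 * sqrt(acc$sigma_x_nm[i]^2 + acc$sigma_y_nm[i]^2) + 5
      if (sqrt(d2[j]) <= tol) ok <- ok + 1
    }
  }
  expect_gt(ok / total, 0.9)

  # empty (offset-only) stack gives an empty table
  empty <- array(cam$offset, dim = c(64, 64, 3))
  expect_equal(nrow(localize_stack(empty, cam, 1.0)), 0)
})

test_that("localizing a translated stack translates the table", {
  cam <- test_camera(64)
  gt <- make_structures(structure_uniform(density_per_um2 = 10),
                        field_nm = 64 * 106.7, seed = 31)
  phys <- photophysics_params(on_rate = 0.01, off_rate = 0.6, bleach_prob = 0,
                              mean_photons = 1200, bg_photons = 5)
  sched <- simulate_blinking(gt, phys, 60, seed = 32)
  stack <- render_frame_stack(sched, gt, cam, 1.0, seed = 33)
  shift <- 3L  # integer-pixel translation of the identical Poisson draws
  shifted <- array(as.integer(cam$offset), dim = dim(stack))
  shifted[(1 + shift):64, , ] <- stack[1:(64 - shift), , ]
  t1 <- localize_stack(stack, cam, 1.0)
  t2 <- localize_stack(shifted, cam, 1.0)
  a1 <- t1[t1$accepted & t1$x_px < 64 - shift - 5, ]
  a2 <- t2[t2$accepted & t2$x_px > shift + 4, ]
  # match by frame and shifted position
  key1 <- paste(a1$frame, round(a1$x_px + shift, 2), round(a1$y_px, 2))
  key2 <- paste(a2$frame, round(a2$x_px, 2), round(a2$y_px, 2))
  expect_gt(length(intersect(key1, key2)) / max(length(key1), 1), 0.95)
})
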