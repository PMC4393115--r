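test_that("make_structures realizes the declared geometry", {
  # zero-spread line stays on its axis with ~density * length points
  gt <- make_structures(structure_line(0, 500, 1000, 500, spread_nm = 0,
                                       density_per_um = 100),
                        field_nm = c(1200, 1200), seed = 1)
  expect_true(all(gt$y_nm == 500))
  expect_true(all(gt$x_nm >= 0 & gt$x_nm <= 1000))
  expect_gt(nrow(gt), 60)   # Poisson(100)
  expect_lt(nrow(gt), 140)

  # ring radii concentrate at radius +/- spread
  gt2 <- make_structures(structure_ring(500, 500, 100, spread_nm = 5, n = 50),
                         field_nm = 1000, seed = 2)
  r <- sqrt((gt2$x_nm - 500)^2 + (gt2$y_nm - 500)^2)
  expect_equal(nrow(gt2), 50)
  expect_true(all(abs(r - 100) < 5 * 5))

  # cluster stays in its disc; uniform fills the field
  gt3 <- make_structures(list(structure_cluster(300, 300, 150, n = 40),
                              structure_uniform(density_per_um2 = 50)),
                         field_nm = 1000, seed = 3)
  cl <- gt3[gt3$type == "cluster", ]
  expect_true(all(sqrt((cl$x_nm - 300)^2 + (cl$y_nm - 300)^2) <= 150))
  expect_true(all(gt3$x_nm >= 0 & gt3$x_nm <= 1000))
})

test_that("make_structures is seed-deterministic and validates geometry", {
  spec <- structure_ring(500, 500, 120, n = 30)
  a <- make_structures(spec, 1000, seed = 7)
  b <- make_structures(spec, 1000, seed = 7)
  c <- make_structures(spec, 1000, seed = 8)
  expect_identical(a$x_nm, b$x_nm)
  expect_false(identical(a$x_nm, c$x_nm))

  expect_error(make_structures(structure_ring(100, 100, 200, n = 5), 1000),
               "outside the field")
  expect_error(make_structures(structure_line(-5, 0, 100, 0, n = 5), 1000),
               "outside the field")
  expect_error(structure_line(0, 0, 100, 0, density_per_um = -1))
})

test_that("blinking follows the two-state Markov stationary duty cycle", {
  gt <- make_structures(structure_uniform(density_per_um2 = 3),
                        field_nm = 10000, seed = 1)
  n_frames <- 4000
  p <- photophysics_params(on_rate = 0.001, off_rate = 0.5, bleach_prob = 0,
                           mean_photons = 800)
  sched <- simulate_blinking(gt, p, n_frames, seed = 2)
  duty <- nrow(sched) / (nrow(gt) * n_frames)
  expected <- 0.001 / (0.001 + 0.5)
  # on-events come in short geometric bursts; allow generous MC slack
  expect_lt(abs(duty - expected) / expected, 0.2)
  # photon counts are Poisson about the mean
  expect_lt(abs(mean(sched$photons) - 800) / 800, 0.05)
})

test_that("blinking respects bleaching and start-dark conventions", {
  gt <- make_structures(structure_uniform(density_per_um2 = 2),
                        field_nm = 8000, seed = 3)
  # bleach probability 1: at most one on-interval per emitter
  sched <- simulate_blinking(gt, photophysics_params(on_rate = 0.05,
                                                     off_rate = 0.5,
                                                     bleach_prob = 1),
                             2000, seed = 4)
  gaps <- tapply(sched$frame, sched$emitter, function(f)
    any(diff(sort(f)) > 1))
  expect_false(any(gaps))

  # on-rate 0 with all emitters starting dark: empty schedule
  empty <- simulate_blinking(gt, photophysics_params(on_rate = 0,
                                                     off_rate = 0.5),
                             500, seed = 5)
  expect_equal(nrow(empty), 0)
})

test_that("inject_residuals thins emitters binomially", {
  gt <- make_structures(structure_uniform(density_per_um2 = 100),
                        field_nm = 10000, seed = 6)
  n <- nrow(gt)
  expect_gt(n, 8000)
  sched <- simulate_blinking(gt, photophysics_params(on_rate = 0.01), 50,
                             seed = 7)
  expect_identical(nrow(inject_residuals(sched, 0, seed = 1)), 0L)
  expect_identical(inject_residuals(sched, 1, seed = 1)$photons,
                   sched$photons)
  kept <- length(attr(inject_residuals(sched, 0.05, seed = 8), "retained"))
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(kept, ci[1])
  expect_lte(kept, ci[2])
})

test_that("frame rendering conserves photons and matches its expectation", {
  cam <- test_camera(32, gain = 20)
  gt <- make_structures(structure_ring(1700, 1700, 200, n = 1),
                        field_nm = 32 * 106.7, seed = 1)
  p <- photophysics_params(on_rate = 1, off_rate = 0, bleach_prob = 0,
                           mean_photons = 1e6, bg_photons = 0)
  sched <- simulate_blinking(gt, p, 1, seed = 2)

  # empty schedule, zero background: every pixel sits at the offset
  blank <- simulate_blinking(gt, photophysics_params(on_rate = 0,
                                                     bg_photons = 0),
                             1, seed = 1)
  st0 <- render_frame_stack(blank, gt, cam, 1.0, noise = FALSE)
  expect_true(all(st0 == cam$offset))

  # noise-free conservation within ADU rounding
  st <- render_frame_stack(sched, gt, cam, 1.0, noise = FALSE)
  expect_lt(abs(sum(adu_to_photons(st[, , 1], cam)) - sched$photons[1]) /
            sched$photons[1], 1e-3)

  # Monte-Carlo mean over noisy renders approaches the noise-free render
  # (camera gain 0.5: ADU quantization contributes at most one gain step)
  cam2 <- test_camera(32)
  p2 <- photophysics_params(on_rate = 1, off_rate = 0, bleach_prob = 0,
                            mean_photons = 2000, bg_photons = 3)
  s2 <- simulate_blinking(gt, p2, 1, seed = 3)
  exp_img <- adu_to_photons(render_frame_stack(s2, gt, cam2, 1.0,
                                               noise = FALSE)[, , 1], cam2)
  acc <- matrix(0, 32, 32)
  n_rep <- 500
  for (k in seq_len(n_rep))
    acc <- acc + adu_to_photons(render_frame_stack(s2, gt, cam2, 1.0,
                                                   seed = 1000 + k)[, , 1],
                                cam2)
  mean_img <- acc / n_rep
  se <- sqrt(pmax(exp_img, 1) / n_rep)
  expect_lt(max(abs(mean_img - exp_img) / (3 * se + cam2$gain)), 1)
})

test_that("simulator outputs are bit-reproducible under a fixed seed", {
  cam <- test_camera(32)
  gt <- make_structures(structure_uniform(density_per_um2 = 30),
                        field_nm = 32 * 106.7, seed = 9)
  p <- photophysics_params(on_rate = 0.01)
  s1 <- simulate_blinking(gt, p, 100, seed = 11)
  s2 <- simulate_blinking(gt, p, 100, seed = 11)
  expect_identical(s1, s2)
  st1 <- render_frame_stack(s1, gt, cam, 1.0, seed = 12)
  st2 <- render_frame_stack(s2, gt, cam, 1.0, seed = 12)
  expect_identical(as.integer(st1), as.integer(st2))
})
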