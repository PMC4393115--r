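test_that("crosstalk computes per-region remaining percentages", {
  set.seed(1)
  before <- loc_table(runif(1000, 0, 2000), runif(1000, 0, 2000))
  # identical tables: 100% everywhere
  ct100 <- crosstalk(before, before, box_nm = 1000, min_before = 50)
  expect_true(all(ct100$regions$pct == 100))

  # 1000 before, 2 after in one box: 0.2%
  after <- before[1:2, ]
  regions <- data.frame(x0 = 0, y0 = 0, x1 = 2000, y1 = 2000)
  ct <- crosstalk(before, after, regions = regions)
  expect_equal(ct$mean_pct, 0.2)

  # only accepted rows count
  before2 <- before; before2$accepted[1:500] <- FALSE
  ct2 <- crosstalk(before2, after, regions = regions)
  expect_equal(ct2$mean_pct, 0.4)
})

test_that("crosstalk is unbiased at the injected survival fractions", {
  # emulates the photodestruction measurement at the published scales
  # (0.2%, ~5%, 12.6%) over a 30-box grid
  gt <- make_structures(structure_uniform(density_per_um2 = 60),
                        field_nm = c(12000, 10000), seed = 2)
  phys <- photophysics_params(on_rate = 0.02, off_rate = 0.5, bleach_prob = 0)
  sched <- simulate_blinking(gt, phys, 40, seed = 3)
  before <- loc_table(gt$x_nm[sched$emitter], gt$y_nm[sched$emitter])
  n_events <- nrow(sched)
  for (f in c(0.002, 0.05, 0.126)) {
    thinned <- inject_residuals(sched, f, seed = round(1000 * f))
    after <- loc_table(gt$x_nm[thinned$emitter], gt$y_nm[thinned$emitter])
    ct <- crosstalk(before, after, box_nm = 2000, min_before = 50)
    expect_gte(ct$n_regions, 25)
    # total-count binomial 99% interval, expressed on the mean percentage
    ci <- qbinom(c(0.005, 0.995), n_events, f) / n_events * 100
    expect_gte(ct$mean_pct, ci[1] - 0.25 * f * 100)
    expect_lte(ct$mean_pct, ci[2] + 0.25 * f * 100)
  }
})

test_that("global_shift recovers known translations and is antisymmetric", {
  set.seed(4)
  tab <- loc_table(runif(3000, 200, 4800), runif(3000, 200, 4800))
  tabT <- tab
  tabT$x_nm <- tabT$x_nm + 20
  tabT$y_nm <- tabT$y_nm - 10
  iA <- render_sr(tab, 10, field_nm = 5200)
  iB <- render_sr(tabT, 10, field_nm = 5200)

  g0 <- global_shift(iA, iA)
  expect_equal(c(g0$dx, g0$dy, g0$magnitude), c(0, 0, 0))

  g <- global_shift(iA, iB)
  expect_lt(abs(g$dx - 20), 2)
  expect_lt(abs(g$dy + 10), 2)

  gr <- global_shift(iB, iA)
  expect_lt(abs(g$dx + gr$dx), 1)
  expect_lt(abs(g$dy + gr$dy), 1)

  expect_error(global_shift(render_sr(loc_table(numeric(), numeric()),
                                      10, 100),
                            render_sr(loc_table(numeric(), numeric()),
                                      10, 100)),
               "featureless")

  # the published example magnitude
  expect_equal(round(shift_magnitude(-8.3, -3.6), 1), 9)
  expect_lt(abs(shift_magnitude(-8.3, -3.6) - 9.1), 0.1)
})

# simulated microtubule segment: localizations scattered around a line
make_segment_data <- function(n, x1, y1, x2, y2, spread = 20, noise = 10,
                              seed = 1) {
  set.seed(seed)
  ang <- atan2(y2 - y1, x2 - x1)
  t <- runif(n); d <- rnorm(n, 0, spread)
  loc_table(x1 + t * (x2 - x1) - sin(ang) * d + rnorm(n, 0, noise),
            y1 + t * (y2 - y1) + cos(ang) * d + rnorm(n, 0, noise))
}

test_that("local_shift measures perpendicular displacement of a segment", {
  seg <- segment_spec(1000, 1000, 4000, 2500)
  A <- make_segment_data(2000, 1000, 1000, 4000, 2500)

  # identity: zero shift within fit noise (< 1 nm at N = 2000)
  ls0 <- local_shift(A, A, seg)
  expect_lt(abs(ls0$shift_nm), 1)

  # known 15 nm perpendicular displacement recovered within 2 nm
  perp <- c(-sin(seg$angle), cos(seg$angle))
  B <- A
  B$x_nm <- B$x_nm + 15 * perp[1]
  B$y_nm <- B$y_nm + 15 * perp[2]
  ls <- local_shift(A, B, seg)
  expect_lt(abs(ls$shift_nm - 15), 2)

  # equivariance: adding a constant perpendicular offset c shifts the
  # estimate by exactly c (to fit tolerance)
  for (c_off in c(-20, 8)) {
    B2 <- A
    B2$x_nm <- B2$x_nm + c_off * perp[1]
    B2$y_nm <- B2$y_nm + c_off * perp[2]
    expect_lt(abs(local_shift(A, B2, seg)$shift_nm - ls0$shift_nm - c_off), 2)
  }

  # horizontal segment: rotation is the identity, pure y displacement
  segH <- segment_spec(500, 2000, 3500, 2000)
  expect_equal(segH$angle, 0)
  H <- make_segment_data(1500, 500, 2000, 3500, 2000, seed = 2)
  H2 <- H; H2$y_nm <- H2$y_nm + 12
  expect_lt(abs(local_shift(H, H2, segH)$shift_nm - 12), 2)

  # too few localizations is an error naming the counts
  expect_error(local_shift(A[1:50, ], A, seg), "too few")
})

test_that("shift_report ties local shifts to the global vector", {
  # segments at several orientations, constant injected shift (3, -4) nm
  segs <- list(segment_spec(1000, 1000, 5000, 1100),   # ~horizontal
               segment_spec(1200, 1500, 1300, 5500),   # ~vertical
               segment_spec(1500, 1500, 4500, 4600))   # diagonal
  tabs <- lapply(seq_along(segs), function(k) {
    s <- segs[[k]]
    make_segment_data(2500, s$x1, s$y1, s$x2, s$y2, seed = 10 + k)
  })
  A <- do.call(rbind, tabs)
  B <- A
  B$x_nm <- B$x_nm + 3
  B$y_nm <- B$y_nm - 4
  rep <- shift_report(A, B, segs, pixel_nm = 10)
  expect_lt(abs(rep$global$dx - 3), 2)
  expect_lt(abs(rep$global$dy + 4), 2)
  # each local shift equals the projection of (3, -4) on the segment
  # perpendicular within 2 standard errors (~1 nm at N = 2500)
  for (k in seq_along(segs)) {
    perp <- c(-sin(segs[[k]]$angle), cos(segs[[k]]$angle))
    expected <- sum(c(3, -4) * perp)
    expect_lt(abs(rep$segments$shift_nm[k] - expected), 2)
  }

  # null dataset: all local shifts are small
  rep0 <- shift_report(A, A, segs, pixel_nm = 10)
  expect_lt(max(abs(rep0$segments$shift_nm)), 1.5)
  expect_equal(rep0$global$magnitude, 0)

  # a segment parallel to the injected shift sees ~zero local shift
  segP <- segment_spec(1000, 1000, 1000 + 3000, 1000 - 4000)
  AP <- make_segment_data(2500, 1000, 1000, 4000, -3000, seed = 99)
  BP <- AP; BP$x_nm <- BP$x_nm + 3; BP$y_nm <- BP$y_nm - 4
  expect_lt(abs(local_shift(AP, BP, segP)$shift_nm), 2)
})
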