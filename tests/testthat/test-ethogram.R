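tank <- tank_geometry()

test_that("freezing fraction handles the textbook extremes", {
  n <- 300; t <- (0:(n - 1)) / 30
  still <- trajectory3d(t, rep(5, n), rep(4, n), rep(6, n))
  expect_equal(freezing_fraction(still, tank), 1)
  # straight swim at 10 cm/s covers 20 cm per 2 s window; only the last
  # few frames (window remainder under 0.2 s) can label as frozen
  n2 <- 80; t2 <- (0:(n2 - 1)) / 30
  line <- trajectory3d(t2, 10 * t2, rep(4, n2), rep(6, n2))
  expect_lt(freezing_fraction(line, tank), 0.1)
})

test_that("freezing matches the exhaustive window-scan oracle on bouts", {
  fr <- 30
  # 4 s frozen / 4 s swimming bouts over 24 s
  segs <- lapply(0:5, function(k) {
    if (k %% 2 == 0) matrix(rep(c(5 + 3 * k, 4, 6), each = 4 * fr), ncol = 3)
    else {
      tt <- seq_len(4 * fr) / fr
      cbind(5 + 3 * (k - 1) + 6 * tt / 4, rep(4, 4 * fr), rep(6, 4 * fr))
    }
  })
  m <- do.call(rbind, segs)
  tr <- trajectory3d((0:(nrow(m) - 1)) / fr, m[, 1], m[, 2], m[, 3],
                     frame_rate = fr)
  ref <- ref_frozen_labels(coords(tr), fr, tank$freeze_radius,
                           tank$freeze_window)
  expect_equal(freezing_fraction(tr, tank), mean(ref, na.rm = TRUE),
               tolerance = 1e-12)
  expect_gt(freezing_fraction(tr, tank), 0.2)
  expect_lt(freezing_fraction(tr, tank), 0.8)
})

test_that("wall following respects the per-view observable boundaries", {
  n <- 60; t <- (0:(n - 1)) / 30
  # centerline path: 4.25 cm from each long wall, outside the 3 cm margin
  mid <- trajectory3d(t, seq(5, 24, length.out = n), rep(4.25, n),
                      rep(6.5, n))
  expect_equal(wall_following_fraction(mid, tank), 0)
  # hugging one long wall at mid depth counts in 3D and top, not front
  hug <- trajectory3d(t, seq(5, 24, length.out = n), rep(1, n),
                      rep(6.5, n))
  expect_equal(wall_following_fraction(hug, tank), 1)
  expect_equal(wall_following_fraction(project(hug, "top"), tank), 1)
  expect_equal(wall_following_fraction(project(hug, "front"), tank), 0)
  # front view at tank center: no y information, far from x walls/bottom
  fv <- track2d(t, rep(14.5, n), rep(6.5, n), view = "front")
  expect_equal(wall_following_fraction(fv, tank), 0)
  # oracle equivalence on random in-tank points, all three views
  set.seed(31)
  tr <- trajectory3d(t, runif(n, 0, 29), runif(n, 0, 8.5), runif(n, 0, 13))
  for (v in c("3D", "top", "front")) {
    obj <- if (v == "3D") tr else project(tr, v)
    expect_equal(wall_following_fraction(obj, tank),
                 mean(ref_wall(coords(obj), v, tank)),
                 info = v)
  }
  expect_error(wall_following_fraction(tr, tank, view = "oblique"))
})

test_that("top-half occupancy is threshold-exact and view-aware", {
  n <- 1800; t <- (0:(n - 1)) / 30
  hi <- trajectory3d(t, rep(10, n), rep(4, n), rep(10, n))
  lo <- trajectory3d(t, rep(10, n), rep(4, n), rep(2, n))
  expect_equal(top_half_fraction(hi, tank), 1)
  expect_equal(top_half_fraction(lo, tank), 0)
  osc <- trajectory3d(t, rep(10, n), rep(4, n),
                      6.5 + 5 * sin(2 * pi * t / 60))
  expect_equal(top_half_fraction(osc, tank), 0.5, tolerance = 2 / n)
  expect_warning(na <- top_half_fraction(project(hi, "top"), tank),
                 "top view")
  expect_true(is.na(na))
})

test_that("peak mean follows the strict-exceedance percentile definition", {
  expect_equal(peak_mean(1:100), mean(91:100))
  expect_equal(peak_mean(1:100), ref_peak_mean(1:100))
  expect_warning(v <- peak_mean(rep(3, 20)), "constant")
  expect_equal(v, 3)
  set.seed(5)
  for (i in 1:10) {
    x <- rexp(50 + i)
    expect_gte(peak_mean(x), mean(x))
    expect_equal(peak_mean(3.7 * x), 3.7 * peak_mean(x))
    expect_equal(peak_mean(x), ref_peak_mean(x), tolerance = 1e-12)
  }
})

test_that("the binned ethogram is stationary under uniform motion", {
  fr <- 30; n <- 360 * fr; t <- (0:(n - 1)) / fr
  # slow constant-speed shuttle along x keeps every bin identical
  x <- 14.5 + 10 * (2 / pi) * asin(sin(2 * pi * t / 120))
  suppressWarnings(tr <- trajectory3d(t, x, rep(4.25, n), rep(6.5, n)))
  e <- compute_ethogram(tr, tank)
  expect_equal(diff(range(e$avg_speed)), 0, tolerance = 1e-6)
  expect_true(all(!e$flagged))
  expect_true(all(e$avg_peak_speed >= e$avg_speed - 1e-9))
})

test_that("all nine measures match the unvectorized reference", {
  fr <- 30
  for (seed in 1:4) {
    tr <- random_walk_traj(500, fr = fr, seed = seed)
    dur <- 500 / fr
    frozen <- ref_frozen_labels(coords(tr), fr, tank$freeze_radius,
                                tank$freeze_window)
    for (v in c("3D", "top", "front")) {
      obj <- if (v == "3D") tr else project(tr, v)
      suppressWarnings(
        e <- compute_ethogram(obj, tank, n_bins = 1, bin_length = dur))
      frozen_v <- ref_frozen_labels(coords(obj), fr, tank$freeze_radius,
                                    tank$freeze_window)
      ref <- ref_ethogram_bin(coords(obj), fr, v, tank, 1:500, frozen_v)
      got <- as.numeric(e[1, ethogram_measures()])
      if (v == "top") {
        expect_true(is.na(got[9]))
        expect_equal(got[-9], unname(ref[-9]), tolerance = 1e-9)
      } else {
        expect_equal(got, unname(ref), tolerance = 1e-9)
      }
    }
  }
})

test_that("locomotion measures from 3D dominate both projections", {
  p <- behavior_params()
  for (seed in 1:3) {
    tr <- simulate_trajectory(p, tank, duration = 120, seed = 600 + seed)
    e3 <- compute_ethogram(tr, tank, n_bins = 2)
    et <- compute_ethogram(project(tr, "top"), tank, n_bins = 2)
    ef <- compute_ethogram(project(tr, "front"), tank, n_bins = 2)
    for (ms in c("avg_speed", "avg_peak_speed", "avg_accel",
                 "avg_peak_accel")) {
      expect_true(all(e3[[ms]] >= et[[ms]] - 1e-9), info = ms)
      expect_true(all(e3[[ms]] >= ef[[ms]] - 1e-9), info = ms)
    }
  }
})

test_that("freezing is translation invariant; occupancy is time reversible", {
  tr <- random_walk_traj(400, seed = 44)
  shifted <- trajectory3d(tr$t, tr$x + 1.5, tr$y - 0.8, tr$z + 2)
  expect_equal(freezing_fraction(shifted, tank), freezing_fraction(tr, tank))
  rev_tr <- trajectory3d(tr$t, rev(tr$x), rev(tr$y), rev(tr$z))
  expect_equal(wall_following_fraction(rev_tr, tank),
               wall_following_fraction(tr, tank))
  expect_equal(top_half_fraction(rev_tr, tank), top_half_fraction(tr, tank))
})

test_that("bins without enough valid data are flagged missing", {
  fr <- 30; n <- 90 * fr; t <- (0:(n - 1)) / fr  # only 1.5 minutes
  x <- 14.5 + 5 * sin(t)
  suppressWarnings(tr <- trajectory3d(t, x, rep(4, n), rep(6, n)))
  expect_warning(e <- compute_ethogram(tr, tank), "shorter")
  expect_false(any(e$flagged[1]))
  expect_true(all(e$flagged[3:6]))
  expect_true(all(is.na(e$avg_speed[3:6])))
})
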