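# Arena fitting, detection, identity linking, calibration

test_that("a drawn circle is recovered within a pixel", {
  xs <- 0:639; ys <- 0:479
  d <- sqrt(outer((ys - 240)^2, (xs - 320)^2, "+"))
  frame <- round(40 + 160 * pmin(pmax(200.5 - d, 0), 1))
  fit <- fit_arena(frame, diameter_mm = 55)
  expect_lt(abs(fit$center_px[1] - 320), 1)
  expect_lt(abs(fit$center_px[2] - 240), 1)
  expect_lt(abs(fit$radius_px - 200), 1)
  expect_equal(fit$px_per_mm, 400 / 55, tolerance = 0.01)
})

test_that("blank or non-circular frames raise a calibration error", {
  expect_error(fit_arena(matrix(128, 100, 100)), class = "snb_calibration_error")
  sq <- matrix(40, 200, 200); sq[50:150, 50:150] <- 200
  expect_error(fit_arena(sq), class = "snb_calibration_error")
})

test_that("an explicitly supplied arena is passed through unchanged", {
  ar <- test_arena()
  traj <- simulate_group(sim_params(n_flies = 2, duration_s = 1, fps = 5, seed = 1))
  fs <- render_frames(traj, render_params(noise_sd = 0))
  dets <- detect_sequence(fs, arena = ar)
  expect_identical(attr(dets, "arena"), ar)
})

test_that("detection finds nothing on background and one accurate blob per fly", {
  ar <- test_arena()
  blank <- matrix(200L, 300, 300)
  expect_equal(nrow(detect_flies(blank, ar)), 0)

  # single fly at a known subpixel position
  traj <- trajectory_set(matrix(3.21, 1, 1), matrix(-7.89, 1, 1), fps = 30,
                         units = "mm", arena = arena_spec(diameter_mm = 55))
  fs <- render_frames(traj, render_params(noise_sd = 0))
  d <- detect_flies(fs$frames[[1]], fs$arena)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_px - (fs$arena$center_px[1] + 3.21 * fs$arena$px_per_mm)), 0.5)
  expect_lt(abs(d$y_px - (fs$arena$center_px[2] - 7.89 * fs$arena$px_per_mm)), 0.5)

  # 16 well-separated flies
  ang <- seq(0, 2 * pi, length.out = 17)[1:16]
  r <- rep(c(12, 22), 8)
  traj16 <- trajectory_set(matrix(r * cos(ang), 1), matrix(r * sin(ang), 1),
                           fps = 30, units = "mm",
                           arena = arena_spec(diameter_mm = 55))
  fs16 <- render_frames(traj16, render_params(noise_sd = 0))
  expect_equal(nrow(detect_flies(fs16$frames[[1]], fs16$arena)), 16)
})

test_that("assignment solver matches the brute-force optimum", {
  set.seed(42)
  for (k in 1:40) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    a <- solve_lap(C)
    expect_equal(sum(C[cbind(seq_len(n), a)]), brute_lap(C)$cost, tolerance = 1e-12)
    expect_true(all(sort(a) == seq_len(n)))
  }
})

test_that("a single clean track is linked as the identity", {
  ar <- test_arena()
  xs <- seq(100, 160, by = 2)
  dets <- det_set(lapply(xs, function(x) c(x, 150)), ar)
  tr <- link_trajectories(dets, n_expected = 1)
  expect_equal(as.vector(tr$x), xs)
  expect_true(all(tr$flag == 0L))
  expect_equal(tr$units, "px")
})

test_that("two tracks passing beyond the gate never swap identities", {
  ar <- test_arena()
  # fly A moves right along y=145, fly B moves left along y=165; they pass
  # mid-sequence with 20 px vertical separation, gate is ~34 px at default
  ta <- seq(80, 220, by = 4); tb <- rev(ta)
  dets <- det_set(Map(function(a, b) rbind(c(a, 145), c(b, 165)), ta, tb), ar)
  tr <- link_trajectories(dets, n_expected = 2, params = link_params())
  expect_equal(as.vector(tr$x[, 1]), ta)
  expect_equal(as.vector(tr$x[, 2]), tb)
  expect_equal(unique(as.vector(tr$y[, 1])), 145)
})

test_that("one dropped detection is linearly interpolated and flagged", {
  ar <- test_arena()
  coords <- lapply(seq(100, 140, by = 4), function(x) c(x, 150))
  coords[[5]] <- matrix(numeric(0), 0, 2)  # drop frame 5
  dets <- det_set(coords, ar)
  tr <- link_trajectories(dets, n_expected = 1)
  expect_equal(tr$flag[5, 1], 1L)
  expect_equal(tr$x[5, 1], (tr$x[4, 1] + tr$x[6, 1]) / 2)
  expect_equal(tr$x[5, 1], 116)
})

test_that("gaps longer than max_gap stay missing", {
  ar <- test_arena()
  coords <- lapply(seq(100, 190, by = 3), function(x) c(x, 150))
  for (i in 10:17) coords[[i]] <- matrix(numeric(0), 0, 2)  # 8-frame gap
  dets <- det_set(coords, ar)
  tr <- link_trajectories(dets, n_expected = 1, params = link_params(max_gap = 5))
  expect_true(all(tr$flag[10:17, 1] == 2L))
  expect_true(all(is.na(tr$x[10:17, 1])))
  expect_equal(tr$flag[18, 1], 0L)
})

test_that("linking is invariant to detection order within frames", {
  ar <- test_arena()
  set.seed(8)
  n <- 5
  base <- cbind(runif(n, 110, 190), runif(n, 110, 190))
  coords <- list(); pos <- base
  for (t in 1:30) {
    pos <- pos + matrix(rnorm(2 * n, 0, 2), n)
    coords[[t]] <- pos
  }
  tr1 <- link_trajectories(det_set(coords, ar), n_expected = n)
  shuffled <- lapply(coords, function(m) m[sample(nrow(m)), , drop = FALSE])
  tr2 <- link_trajectories(det_set(shuffled, ar), n_expected = n)
  # same set of tracks up to column order (init order may differ)
  perm <- evaluate_tracking(calibrate(tr2, ar), calibrate(tr1, ar))$perm
  expect_equal(tr2$x, tr1$x[, perm])
  expect_equal(tr2$y, tr1$y[, perm])
})

test_that("too few detections at start raises an initialization error", {
  ar <- test_arena()
  coords <- replicate(10, rbind(c(120, 150)), simplify = FALSE)
  expect_error(link_trajectories(det_set(coords, ar), n_expected = 3),
               class = "snb_track_error")
})

test_that("calibration maps center to origin, scales radii, and round-trips", {
  ar <- test_arena()
  X <- matrix(c(ar$center_px[1], ar$center_px[1] + ar$radius_px, 170), 3, 1)
  Y <- matrix(c(ar$center_px[2], ar$center_px[2], 120), 3, 1)
  tr <- trajectory_set(X, Y, fps = 30, units = "px")
  mm <- calibrate(tr, ar)
  expect_equal(mm$x[1, 1], 0)
  expect_equal(mm$y[1, 1], 0)
  expect_equal(mm$x[2, 1], ar$diameter_mm / 2)
  set.seed(3)
  rnd <- trajectory_set(matrix(runif(40, 50, 250), 20, 2),
                        matrix(runif(40, 50, 250), 20, 2), fps = 30, units = "px")
  back <- decalibrate(calibrate(rnd, ar), ar)
  expect_lt(max(abs(back$x - rnd$x)), 1e-9)
  expect_lt(max(abs(back$y - rnd$y)), 1e-9)
})

test_that("rendered recordings are recovered with subpixel accuracy end to end", {
  p <- sim_params(n_flies = 8, duration_s = 6, fps = 15, seed = 31,
                  repulsion_radius_mm = 8, attraction = 0)
  truth <- simulate_group(p)
  res <- render_and_track(truth, render_params(noise_sd = 0), chunk_size = 50)
  expect_true(all(res$detections_per_frame == 8))
  ev <- evaluate_tracking(res$traj, truth, px_per_mm = res$arena$px_per_mm)
  expect_lt(ev$rmse_px, 1)
  expect_equal(ev$swaps, 0)
  expect_equal(ev$n_valid, 8 * n_frames(truth))
})
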