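# Group phenotype metrics against naive-loop oracles and exact cases

two_fly <- function(T = 10) {
  trajectory_set(matrix(c(rep(0, T), rep(3, T)), T, 2),
                 matrix(c(rep(0, T), rep(4, T)), T, 2),
                 fps = 30, units = "mm")
}

test_that("two flies at (0,0) and (3,4) have SD 5 at every frame", {
  sds <- social_distance(two_fly())
  expect_equal(as.vector(sds$per_fly), rep(5, 20))
  expect_equal(sds$overall, 5)
  expect_equal(social_distance(two_fly(), mode = "nearest")$overall, 5)
})

test_that("coincident flies have SD 0 and unit-square corners ~1.13807", {
  T <- 4
  co <- trajectory_set(matrix(2, T, 3), matrix(-1, T, 3), fps = 30, units = "mm")
  expect_equal(social_distance(co)$overall, 0)
  sq <- trajectory_set(matrix(rep(c(0, 1, 0, 1), each = T), T, 4),
                       matrix(rep(c(0, 0, 1, 1), each = T), T, 4),
                       fps = 30, units = "mm")
  sds <- social_distance(sq)
  expect_equal(sds$overall, (2 + sqrt(2)) / 3, tolerance = 1e-12)
  expect_equal(as.vector(sds$per_fly), rep((2 + sqrt(2)) / 3, 4 * T))
  ctr <- centroid_series(sq)
  expect_equal(ctr$x_mm, rep(0.5, T))
  expect_equal(ctr$y_mm, rep(0.5, T))
})

test_that("SD requires at least two flies", {
  one <- trajectory_set(matrix(0, 5, 1), matrix(0, 5, 1), fps = 30, units = "mm")
  expect_error(social_distance(one), "single fly", class = "snb_metric_error")
})

test_that("unit steps give exact walking speed and travel distances", {
  T <- 31
  tr <- trajectory_set(matrix(0:(T - 1), T, 1), matrix(0, T, 1),
                       fps = 30, units = "mm")
  expect_equal(walking_speed(tr)$mean, 30)
  trav <- travel_distance(tr)
  expect_equal(trav[T, 1], T - 1)
  expect_true(all(diff(trav[, 1]) >= 0))
  # closed loop: path length, not net displacement
  th <- seq(0, 2 * pi, length.out = 101)
  loop <- trajectory_set(matrix(10 * cos(th), 101, 1),
                         matrix(10 * sin(th), 101, 1), fps = 30, units = "mm")
  expect_gt(travel_distance(loop)[101, 1], 62)
  expect_error(walking_speed(trajectory_set(matrix(0, 1, 1), matrix(0, 1, 1),
                                            fps = 30, units = "mm")),
               class = "snb_metric_error")
})

test_that("centroid velocity matches hand quantiles and exact displacement", {
  # stationary centroid -> 0 under both estimators
  still <- two_fly(40)
  expect_equal(as.numeric(centroid_velocity(still)), 0)
  expect_equal(as.numeric(centroid_velocity(still, estimator = "displacement")), 0)
  # Q4 x-positions 0..9, y constant: IQR by linear interpolation
  T <- 40
  x <- c(rep(0, 30), 0:9)
  tr <- trajectory_set(matrix(x, T, 1), matrix(1, T, 1), fps = 30, units = "mm")
  got <- as.numeric(centroid_velocity(tr))
  expect_equal(got, (oracle_quantile(0:9, 0.75) - oracle_quantile(0:9, 0.25)) / 2)
  expect_equal(got, 4.5 / 2)
  # centroid advancing 0.1 mm/frame at 30 fps -> 3 mm/s
  adv <- trajectory_set(matrix(seq(0, by = 0.1, length.out = 40), 40, 1),
                        matrix(0, 40, 1), fps = 30, units = "mm")
  expect_equal(as.numeric(centroid_velocity(adv, estimator = "displacement")), 3)
})

test_that("quarter means partition frames as floor(kT/4) half-open bins", {
  expect_equal(unname(quarter_summary(rep(7, 9))), rep(7, 4))
  for (T in c(9, 10, 11, 12, 4500 * 4)) {
    ramp <- seq_len(T) - 1
    expect_equal(unname(quarter_summary(ramp)), oracle_quarter_means(ramp))
  }
  # 600 s at 30 fps: quarters are 4500-frame bins
  idx <- rep(0, 18000); idx[4501:9000] <- 1
  expect_equal(unname(quarter_summary(idx)), c(0, 1, 0, 0))
  expect_error(quarter_summary(1:3), class = "snb_metric_error")
})

test_that("all metrics match independent naive-loop oracles on random sets", {
  for (s in 1:5) {
    tr <- rand_traj(16, 200, seed = s)
    sds <- social_distance(tr)
    ora <- oracle_sd(tr)
    expect_lt(max(abs(sds$per_fly - ora$per_fly)), 1e-9)
    expect_lt(abs(sds$overall - ora$overall), 1e-9)
    expect_lt(max(abs(social_distance(tr, "nearest")$per_fly -
                      oracle_nearest_sd(tr))), 1e-9)
    expect_lt(abs(walking_speed(tr)$mean - oracle_speed_mean(tr)), 1e-9)
    expect_lt(max(abs(travel_distance(tr)[200, ] - oracle_travel_final(tr))), 1e-9)
    expect_lt(abs(as.numeric(centroid_velocity(tr)) -
                  oracle_iqr_dispersion_q4(tr)), 1e-9)
    expect_lt(abs(as.numeric(centroid_velocity(tr, estimator = "displacement")) -
                  oracle_disp_q4(tr)), 1e-9)
    expect_equal(oracle_centroid(tr, 37),
                 unlist(centroid_series(tr)[37, c("x_mm", "y_mm")],
                        use.names = FALSE), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to rigid motion and equivariant to scaling", {
  tr <- rand_traj(10, 120, seed = 9)
  rot <- rigid_transform(tr, theta = 0.83, dx = 4.2, dy = -11)
  expect_lt(abs(social_distance(rot)$overall - social_distance(tr)$overall), 1e-9)
  expect_lt(abs(walking_speed(rot)$mean - walking_speed(tr)$mean), 1e-9)
  expect_lt(max(abs(travel_distance(rot) - travel_distance(tr))), 1e-9)
  expect_lt(abs(as.numeric(centroid_velocity(rot, estimator = "displacement")) -
                as.numeric(centroid_velocity(tr, estimator = "displacement"))), 1e-9)
  # IQR dispersion is rotation-covariant only in distribution, but exact under
  # pure translation
  sh <- rigid_transform(tr, 0, 5, 5)
  expect_lt(abs(as.numeric(centroid_velocity(sh)) -
                as.numeric(centroid_velocity(tr))), 1e-9)
  sc <- scale_traj(tr, 2.5)
  expect_equal(social_distance(sc)$overall, 2.5 * social_distance(tr)$overall,
               tolerance = 1e-12)
  expect_equal(walking_speed(sc)$mean, 2.5 * walking_speed(tr)$mean,
               tolerance = 1e-12)
  expect_equal(as.numeric(centroid_velocity(sc)),
               2.5 * as.numeric(centroid_velocity(tr)), tolerance = 1e-12)
})

test_that("group outputs are invariant to fly relabeling", {
  tr <- rand_traj(8, 60, seed = 13)
  set.seed(77)
  pm <- permute_flies(tr, sample(8))
  expect_lt(abs(social_distance(pm)$overall - social_distance(tr)$overall), 1e-12)
  expect_lt(abs(walking_speed(pm)$mean - walking_speed(tr)$mean), 1e-12)
  expect_equal(sort(travel_distance(pm)[60, ]), sort(travel_distance(tr)[60, ]))
  expect_equal(centroid_series(pm)$x_mm, centroid_series(tr)$x_mm)
})

test_that("missing samples are excluded, not imputed", {
  T <- 10
  X <- matrix(c(rep(0, T), rep(3, T), rep(10, T)), T, 3)
  Y <- matrix(c(rep(0, T), rep(4, T), rep(0, T)), T, 3)
  FL <- matrix(0L, T, 3)
  FL[, 3] <- 2L; X[, 3] <- NA; Y[, 3] <- NA       # fly 3 never observed
  FL[4, 2] <- 2L; X[4, 2] <- NA; Y[4, 2] <- NA    # fly 2 missing at frame 4
  tr <- trajectory_set(X, Y, fps = 30, flag = FL, units = "mm")
  sds <- social_distance(tr)
  expect_false(sds$valid_frames[4])               # only one valid fly there
  expect_equal(sds$overall, 5)
  ws <- walking_speed(tr)
  expect_true(is.na(ws$per_fly[3, 2]) && is.na(ws$per_fly[4, 2]))
  expect_equal(ws$mean, 0)
  expect_equal(travel_distance(tr)[T, 2], 0)
})

test_that("group_metrics bundles deterministically and handles single flies", {
  tr <- simulate_group(sim_params(n_flies = 5, duration_s = 10, fps = 10, seed = 2))
  a <- group_metrics(tr); b <- group_metrics(tr)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$centroid_velocity, a$centroid_velocity_iqr)
  one <- simulate_group(sim_params(n_flies = 1, duration_s = 10, fps = 10, seed = 2))
  gm1 <- group_metrics(one)
  expect_false(gm1$sd_applicable)
  expect_true(is.na(gm1$sd_overall))
  expect_true(is.finite(gm1$walking_speed))
})

test_that("the 75% maze arrival quorum is the ceiling of the fraction", {
  expect_identical(maze_arrival_quorum(16), 12L)
  expect_identical(maze_arrival_quorum(10), 8L)
  expect_identical(maze_arrival_quorum(12, 0.5), 6L)
})
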