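# Group phenotypes: social distance, walking speed, centroid dynamics,
# quarter summaries, travel distance.

metric_stop <- function(fmt, ...) snb_stop("snb_metric_error", fmt, ...)

#' Social distance (SD)
#'
#' Per fly and frame, SD is the mean Euclidean distance from the focal fly to
#' every other fly with a valid position in that frame (`mode =
#' "mean_pairwise"`, the default), or the distance to the nearest other fly
#' (`mode = "nearest"`, for sensitivity analysis). The per-frame group SD is
#' the arithmetic mean of the per-fly SDs; the overall group SD is the
#' unweighted time average of the per-frame group SD over valid frames
#' (frames with fewer than two valid flies are excluded, not imputed).
#' Interpolated samples count as positions; missing samples do not.
#'
#' @param traj a [trajectory_set()] with at least two flies.
#' @param mode SD definition, see above.
#' @return An object of class `sd_series`: list with `per_fly` (`T x n`
#'   matrix, mm), `group` (per-frame mean, mm), `overall` (mm),
#'   `valid_frames` (logical) and `mode`.
#' @examples
#' traj <- simulate_group(sim_params(n_flies = 4, duration_s = 5, seed = 1))
#' social_distance(traj)$overall
#' @export
social_distance <- function(traj, mode = c("mean_pairwise", "nearest")) {
  stopifnot(inherits(traj, "trajectory_set"))
  mode <- match.arg(mode)
  n <- n_flies(traj); T_ <- n_frames(traj)
  if (n < 2L) metric_stop("SD undefined for a single fly")
  v <- valid_mask(traj)
  acc <- matrix(0, T_, n)
  cnt <- matrix(0L, T_, n)
  nn <- if (mode == "nearest") matrix(Inf, T_, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- v[, i] & v[, j]
    if (!any(ok)) next
    d <- sqrt((traj$x[ok, i] - traj$x[ok, j])^2 + (traj$y[ok, i] - traj$y[ok, j])^2)
    acc[ok, i] <- acc[ok, i] + d; acc[ok, j] <- acc[ok, j] + d
    cnt[ok, i] <- cnt[ok, i] + 1L; cnt[ok, j] <- cnt[ok, j] + 1L
    if (mode == "nearest") {
      nn[ok, i] <- pmin(nn[ok, i], d); nn[ok, j] <- pmin(nn[ok, j], d)
    }
  }
  per_fly <- if (mode == "mean_pairwise") acc / cnt else nn
  per_fly[cnt == 0L] <- NA_real_
  valid_frames <- rowSums(v) >= 2L
  group <- rowMeans(per_fly, na.rm = TRUE)
  group[!valid_frames] <- NA_real_
  if (!any(valid_frames)) metric_stop("no frame has two or more valid flies")
  structure(list(per_fly = per_fly, group = group,
                 overall = mean(group[valid_frames]),
                 valid_frames = valid_frames, mode = mode,
                 times = traj$times, fps = traj$fps),
            class = "sd_series")
}

#' @export
print.sd_series <- function(x, ...) {
  cat(sprintf("<sd_series> mode %s, %d frames, overall group SD %.3f mm\n",
              x$mode, length(x$group), x$overall))
  invisible(x)
}

#' Plot the group social distance over time
#' @param x an `sd_series`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sd_series <- function(x, ...) {
  plot(x$times, x$group, type = "l", xlab = "time (s)",
       ylab = "group SD (mm)", ...)
  abline(h = x$overall, lty = 2, col = "grey40")
  invisible(x)
}

#' Walking speed
#'
#' Per fly, the speed at step t is `|position(t) - position(t-1)| * fps`,
#' optionally after centered moving-average smoothing of the positions.
#' Steps with a missing endpoint are excluded; interpolated samples are
#' included. The group mean averages over all flies and valid steps.
#'
#' @param traj a [trajectory_set()] with at least two frames.
#' @param smooth_window odd moving-average window (frames) applied to the
#'   positions before differencing; 1 (default) disables smoothing.
#' @return List with `per_fly` (`(T-1) x n` matrix, mm/s), `group`
#'   (per-step mean across flies) and `mean` (scalar, mm/s).
#' @export
walking_speed <- function(traj, smooth_window = 1L) {
  stopifnot(inherits(traj, "trajectory_set"))
  T_ <- n_frames(traj)
  if (T_ < 2L) metric_stop("walking speed needs at least two frames")
  check_number(smooth_window, "smooth_window", min = 1, integer = TRUE)
  if (smooth_window %% 2L == 0L) stop_param("smooth_window", "must be odd")
  x <- traj$x; y <- traj$y
  x[!valid_mask(traj)] <- NA; y[!valid_mask(traj)] <- NA
  if (smooth_window > 1L) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- function(m) apply(m, 2L, function(col) {
      s <- stats::filter(col, k, sides = 2)
      s[is.na(s)] <- col[is.na(s)]   # window shrinks to raw value at edges/gaps
      as.numeric(s)
    })
    x <- sm(x); y <- sm(y)
  }
  per_fly <- sqrt(diff(x)^2 + diff(y)^2) * traj$fps
  per_fly <- matrix(per_fly, nrow = T_ - 1L)
  if (!any(!is.na(per_fly))) metric_stop("no valid displacement steps")
  group <- rowMeans(per_fly, na.rm = TRUE)
  group[!is.finite(group)] <- NA_real_
  list(per_fly = per_fly, group = group,
       mean = mean(per_fly, na.rm = TRUE))
}

#' Per-frame group centroid
#'
#' Arithmetic mean of the valid fly positions in each frame; frames with no
#' valid fly give `NA`.
#'
#' @param traj a [trajectory_set()].
#' @return data.frame with `frame` (0-based), `time_s`, `x_mm`, `y_mm`,
#'   `n_valid`.
#' @export
centroid_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  v <- valid_mask(traj)
  x <- traj$x; y <- traj$y
  x[!v] <- NA; y[!v] <- NA
  nv <- rowSums(v)
  data.frame(frame = seq_len(nrow(x)) - 1L, time_s = traj$times,
             x_mm = rowMeans(x, na.rm = TRUE) * ifelse(nv > 0, 1, NA),
             y_mm = rowMeans(y, na.rm = TRUE) * ifelse(nv > 0, 1, NA),
             n_valid = nv)
}

quarter_bins <- function(T_, k = 4L) {
  # half-open bins [floor(qT/k), floor((q+1)T/k)) on 0-based frames
  lapply(seq_len(k) - 1L, function(q)
    seq.int(floor(q * T_ / k) + 1L, floor((q + 1L) * T_ / k)))
}

#' Group centroid velocity (fourth-quarter statistic)
#'
#' The third group phenotype, computed on the fourth quarter of the
#' recording, where clustering is most evident. Two estimators:
#' `"iqr_dispersion"` (default) is the mean of the interquartile ranges of
#' the centroid's x and y coordinates over the window (mm); `"displacement"`
#' is the mean per-frame centroid speed (mm/s). Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7); the
#' estimator used is recorded on the result.
#'
#' @param traj a [trajectory_set()].
#' @param window `"q4"` (default), `"all"`, or a vector of 1-based frame
#'   indices.
#' @param estimator see above.
#' @return Scalar with attributes `estimator` and `window_frames`.
#' @export
centroid_velocity <- function(traj, window = "q4",
                              estimator = c("iqr_dispersion", "displacement")) {
  stopifnot(inherits(traj, "trajectory_set"))
  estimator <- match.arg(estimator)
  T_ <- n_frames(traj)
  idx <- if (identical(window, "q4")) quarter_bins(T_)[[4L]]
         else if (identical(window, "all")) seq_len(T_)
         else as.integer(window)
  if (!length(idx)) metric_stop("empty centroid-velocity window")
  ctr <- centroid_series(traj)
  cx <- ctr$x_mm[idx]; cy <- ctr$y_mm[idx]
  ok <- is.finite(cx) & is.finite(cy)
  if (!any(ok)) metric_stop("no valid centroid in the requested window")
  val <- if (estimator == "iqr_dispersion") {
    (diff(quantile(cx[ok], c(0.25, 0.75), names = FALSE, type = 7)) +
     diff(quantile(cy[ok], c(0.25, 0.75), names = FALSE, type = 7))) / 2
  } else {
    if (sum(ok) < 2L) metric_stop("displacement estimator needs >= 2 centroid samples")
    step <- sqrt(diff(cx)^2 + diff(cy)^2) * traj$fps
    mean(step, na.rm = TRUE)
  }
  structure(val, estimator = estimator, window_frames = range(idx))
}

#' Quarter-averaged summary of a per-frame series
#'
#' Means of the valid samples within four consecutive equal time bins
#' (half-open, boundaries at `floor(k * T / 4)`), the Q1-Q4 summaries used
#' for within-recording dynamics.
#'
#' @param series numeric per-frame vector (length T >= 4).
#' @return Named numeric vector `Q1`..`Q4`.
#' @export
quarter_summary <- function(series) {
  T_ <- length(series)
  if (T_ < 4L) metric_stop("quarter summary needs at least 4 samples")
  vapply(quarter_bins(T_), function(idx) mean(series[idx], na.rm = TRUE),
         numeric(1)) |> setNames(paste0("Q", 1:4))
}

#' Cumulative travel distance
#'
#' Running per-fly sum of stepwise displacements (path length, not net
#' displacement). Steps with a missing endpoint contribute zero, so the
#' series is monotone nondecreasing. Note this is the one output sensitive
#' to tracker identity swaps.
#'
#' @param traj a [trajectory_set()] with at least two frames.
#' @return `T x n` matrix of cumulative distance (mm), first row zero.
#' @export
travel_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (n_frames(traj) < 2L) metric_stop("travel distance needs at least two frames")
  v <- valid_mask(traj)
  x <- traj$x; y <- traj$y
  x[!v] <- NA; y[!v] <- NA
  step <- sqrt(diff(x)^2 + diff(y)^2)
  step[is.na(step)] <- 0
  apply(rbind(0, step), 2L, cumsum)
}

#' All group phenotypes for one recording
#'
#' Bundles the recording's phenotype vector: overall SD, mean walking speed,
#' centroid velocity (both estimators; `centroid_velocity` holds the
#' configured default), quarter summaries of group SD and walking speed, and
#' per-fly travel distance. Single-fly recordings (the single-fly locomotion
#' mode) get speed/travel metrics with SD fields `NA`.
#'
#' @param traj a calibrated [trajectory_set()] in mm.
#' @param sd_mode SD definition, see [social_distance()].
#' @param cv_estimator default centroid-velocity estimator, see
#'   [centroid_velocity()].
#' @param smooth_window speed smoothing window, see [walking_speed()].
#' @return An object of class `group_metrics` (also a one-row data.frame via
#'   [as.data.frame()]).
#' @export
group_metrics <- function(traj, sd_mode = "mean_pairwise",
                          cv_estimator = "iqr_dispersion", smooth_window = 1L) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- n_flies(traj); T_ <- n_frames(traj)
  sd_applicable <- n >= 2L
  sds <- if (sd_applicable) social_distance(traj, mode = sd_mode)
  ws <- walking_speed(traj, smooth_window = smooth_window)
  cv_iqr <- as.numeric(centroid_velocity(traj, estimator = "iqr_dispersion"))
  cv_disp <- as.numeric(centroid_velocity(traj, estimator = "displacement"))
  trav <- travel_distance(traj)
  res <- list(
    n_flies = n, n_frames = T_, fps = traj$fps,
    duration_s = T_ / traj$fps,
    sd_overall = if (sd_applicable) sds$overall else NA_real_,
    sd_quarters = if (sd_applicable) quarter_summary(sds$group)
                  else rep(NA_real_, 4L) |> setNames(paste0("Q", 1:4)),
    walking_speed = ws$mean,
    speed_quarters = quarter_summary(c(NA, ws$group)),
    centroid_velocity = if (cv_estimator == "iqr_dispersion") cv_iqr else cv_disp,
    centroid_velocity_iqr = cv_iqr,
    centroid_velocity_disp = cv_disp,
    travel_final = trav[T_, ],
    travel_mean = mean(trav[T_, ]),
    valid_frame_fraction = mean(valid_mask(traj)),
    sd_applicable = sd_applicable,
    params = list(sd_mode = sd_mode, cv_estimator = cv_estimator,
                  smooth_window = smooth_window)
  )
  structure(res, class = "group_metrics")
}

#' @export
print.group_metrics <- function(x, ...) {
  cat(sprintf("<group_metrics> %d flies, %.1f s @ %g fps\n",
              x$n_flies, x$duration_s, x$fps))
  cat(sprintf("  SD overall      : %s mm  (Q1 %.2f -> Q4 %.2f)\n",
              if (x$sd_applicable) sprintf("%.3f", x$sd_overall) else "n/a",
              x$sd_quarters[1L], x$sd_quarters[4L]))
  cat(sprintf("  walking speed   : %.3f mm/s\n", x$walking_speed))
  cat(sprintf("  centroid vel.   : %.3f (%s; iqr %.3f mm, disp %.3f mm/s)\n",
              x$centroid_velocity, x$params$cv_estimator,
              x$centroid_velocity_iqr, x$centroid_velocity_disp))
  cat(sprintf("  travel distance : %.1f mm (mean per fly)\n", x$travel_mean))
  invisible(x)
}

#' @export
as.data.frame.group_metrics <- function(x, ...) {
  data.frame(
    n_flies = x$n_flies, duration_s = x$duration_s, fps = x$fps,
    sd_overall = x$sd_overall,
    sd_q1 = x$sd_quarters[[1L]], sd_q2 = x$sd_quarters[[2L]],
    sd_q3 = x$sd_quarters[[3L]], sd_q4 = x$sd_quarters[[4L]],
    walking_speed = x$walking_speed,
    speed_q1 = x$speed_quarters[[1L]], speed_q2 = x$speed_quarters[[2L]],
    speed_q3 = x$speed_quarters[[3L]], speed_q4 = x$speed_quarters[[4L]],
    centroid_velocity = x$centroid_velocity,
    centroid_velocity_iqr = x$centroid_velocity_iqr,
    centroid_velocity_disp = x$centroid_velocity_disp,
    travel_mean = x$travel_mean,
    valid_frame_fraction = x$valid_frame_fraction
  )
}

#' Maze 75%-arrival quorum
#'
#' Number of flies that must reach the food for the "75% arrival" latency of
#' a group to be scored: the smallest integer at least `fraction * n_flies`.
#' For the standard 16-fly maze test this is 12 flies.
#'
#' @param n_flies group size.
#' @param fraction arrival fraction (default 0.75).
#' @return Integer quorum.
#' @examples
#' maze_arrival_quorum(16) # 12
#' @export
maze_arrival_quorum <- function(n_flies, fraction = 0.75) {
  check_number(n_flies, "n_flies", min = 1, integer = TRUE)
  check_number(fraction, "fraction", min = 0, max = 1, strict_min = TRUE)
  as.integer(ceiling(fraction * n_flies))
}
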