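# Independent naive-loop oracles. These deliberately share no code with the
# package implementation: per-frame dist() calls, explicit loops, and
# hand-written quantile interpolation.

rand_traj <- function(n = 16, T = 200, seed = 1, fps = 30, scale = 25) {
  set.seed(seed)
  trajectory_set(matrix(runif(T * n, -scale, scale), T, n),
                 matrix(runif(T * n, -scale, scale), T, n),
                 fps = fps, units = "mm",
                 arena = arena_spec(diameter_mm = 4 * scale))
}

oracle_sd <- function(traj) {
  T_ <- nrow(traj$x); n <- ncol(traj$x)
  per_fly <- matrix(NA_real_, T_, n)
  group <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    D <- as.matrix(dist(cbind(traj$x[t, ], traj$y[t, ])))
    for (i in seq_len(n)) per_fly[t, i] <- mean(D[i, -i])
    group[t] <- mean(per_fly[t, ])
  }
  list(per_fly = per_fly, group = group, overall = mean(group))
}

oracle_nearest_sd <- function(traj) {
  T_ <- nrow(traj$x); n <- ncol(traj$x)
  per_fly <- matrix(NA_real_, T_, n)
  for (t in seq_len(T_)) {
    D <- as.matrix(dist(cbind(traj$x[t, ], traj$y[t, ])))
    for (i in seq_len(n)) per_fly[t, i] <- min(D[i, -i])
  }
  per_fly
}

oracle_speed_mean <- function(traj) {
  total <- 0; count <- 0L
  for (i in seq_len(ncol(traj$x))) for (t in 2:nrow(traj$x)) {
    step <- sqrt((traj$x[t, i] - traj$x[t - 1, i])^2 +
                 (traj$y[t, i] - traj$y[t - 1, i])^2)
    total <- total + step * traj$fps
    count <- count + 1L
  }
  total / count
}

oracle_travel_final <- function(traj) {
  n <- ncol(traj$x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (t in 2:nrow(traj$x))
      s <- s + sqrt((traj$x[t, i] - traj$x[t - 1, i])^2 +
                    (traj$y[t, i] - traj$y[t - 1, i])^2)
    out[i] <- s
  }
  out
}

oracle_centroid <- function(traj, t) {
  c(mean(traj$x[t, ]), mean(traj$y[t, ]))
}

# linear-interpolation quantile, written out by hand
oracle_quantile <- function(v, p) {
  v <- sort(v); n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_iqr_dispersion_q4 <- function(traj) {
  T_ <- nrow(traj$x)
  idx <- (floor(3 * T_ / 4) + 1):T_
  cx <- sapply(idx, function(t) mean(traj$x[t, ]))
  cy <- sapply(idx, function(t) mean(traj$y[t, ]))
  ((oracle_quantile(cx, 0.75) - oracle_quantile(cx, 0.25)) +
   (oracle_quantile(cy, 0.75) - oracle_quantile(cy, 0.25))) / 2
}

oracle_disp_q4 <- function(traj) {
  T_ <- nrow(traj$x)
  idx <- (floor(3 * T_ / 4) + 1):T_
  cx <- sapply(idx, function(t) mean(traj$x[t, ]))
  cy <- sapply(idx, function(t) mean(traj$y[t, ]))
  mean(sqrt(diff(cx)^2 + diff(cy)^2)) * traj$fps
}

oracle_quarter_means <- function(series) {
  T_ <- length(series)
  out <- numeric(4)
  for (q in 0:3) {
    idx <- (floor(q * T_ / 4) + 1):floor((q + 1) * T_ / 4)
    out[q + 1] <- mean(series[idx])
  }
  out
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# exhaustive-permutation Spearman oracle (base-R ranks + Pearson)
oracle_spearman_exact <- function(x, y) {
  rho <- suppressWarnings(cor(rank(x), rank(y)))
  perms <- all_perms(seq_along(y))
  rhos <- vapply(perms, function(p)
    suppressWarnings(cor(rank(x), rank(y[p]))), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

brute_lap <- function(C) {
  n <- nrow(C)
  best <- Inf; bp <- NULL
  rec <- function(used, cur, cost) {
    i <- length(cur) + 1L
    if (cost >= best) return()
    if (i > n) { best <<- cost; bp <<- cur; return() }
    for (j in seq_len(n)) if (!used[j])
      rec(replace(used, j, TRUE), c(cur, j), cost + C[i, j])
  }
  rec(rep(FALSE, n), integer(0), 0)
  list(cost = best, perm = bp)
}

# apply a rigid rotation + translation to a trajectory
rigid_transform <- function(traj, theta, dx, dy) {
  out <- traj
  out$x <- cos(theta) * traj$x - sin(theta) * traj$y + dx
  out$y <- sin(theta) * traj$x + cos(theta) * traj$y + dy
  out
}

scale_traj <- function(traj, c_) {
  out <- traj
  out$x <- traj$x * c_; out$y <- traj$y * c_
  out
}

permute_flies <- function(traj, perm) {
  out <- traj
  out$x <- traj$x[, perm, drop = FALSE]
  out$y <- traj$y[, perm, drop = FALSE]
  out$flag <- traj$flag[, perm, drop = FALSE]
  out
}

# build a detection_set from plain per-frame coordinate lists
det_set <- function(coords, arena, fps = 30) {
  structure(lapply(coords, function(m) {
    m <- matrix(m, ncol = 2)
    data.frame(x_px = m[, 1], y_px = m[, 2],
               area_px = rep(40, nrow(m)), mean_intensity = rep(60, nrow(m)))
  }), class = "detection_set", arena = arena, fps = fps)
}

test_arena <- function() arena_spec(center_px = c(150, 150), radius_px = 137.5,
                                    diameter_mm = 55)
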