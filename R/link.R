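# Linear assignment (Jonker-Volgenant style shortest augmenting path) and
# frame-to-frame identity linking.

#' Solve the linear assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix via shortest
#' augmenting paths with dual potentials (O(n^3)). Deterministic: on exactly
#' equal total cost the lowest-index column is reached first and wins.
#'
#' @param cost square numeric matrix (finite; use a large penalty for
#'   forbidden pairs).
#' @return Integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) stop_param("cost", "matrix must be square")
  if (!all(is.finite(cost))) stop_param("cost", "costs must be finite")
  if (n == 0L) return(integer(0))
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials, v[1] = virtual column 0
  p <- integer(n + 1L)       # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])                     # unvisited real columns
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      vis <- which(used)                            # 1-based: columns vis-1
      rows <- p[vis]
      u[rows] <- u[rows] + delta
      v[vis] <- v[vis] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) a[p[j + 1L]] <- j
  a
}

# Rectangular matching with opt-out: n tracks x m detections. Pads to a
# square (n+m) problem where every row/column can instead match a dummy at
# `unmatched_cost`. Returns match[i] in 1..m or NA (unmatched).
lap_match <- function(cost, unmatched_cost, big = 1e12) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  k <- n + m
  C <- matrix(big, k, k)
  C[seq_len(n), seq_len(m)] <- pmin(cost, big)
  for (i in seq_len(n)) C[i, m + i] <- unmatched_cost
  for (j in seq_len(m)) C[n + j, j] <- unmatched_cost
  C[(n + 1L):k, (m + 1L):k] <- 0
  a <- solve_lap(C)
  match <- a[seq_len(n)]
  match[match > m] <- NA_integer_
  # a dummy-padded optimum never uses a forbidden (big) real pair
  real <- which(!is.na(match))
  if (length(real)) {
    bad <- cost[cbind(real, match[real])] >= big
    match[real[bad]] <- NA_integer_
  }
  match
}

#' Linking parameters
#'
#' @param gate_body_lengths maximum allowed per-frame displacement, in body
#'   lengths (default 5: generous for walking flies at phone frame rates).
#' @param max_gap longest detection gap (frames) bridged by linear
#'   interpolation; longer gaps stay `missing`.
#' @param body_length_mm fly body length used to convert the gate to pixels.
#' @return A list of class `link_params`.
#' @export
link_params <- function(gate_body_lengths = 5, max_gap = 5, body_length_mm = 2.5) {
  check_number(gate_body_lengths, "gate_body_lengths", min = 0, strict_min = TRUE)
  check_number(max_gap, "max_gap", min = 0, integer = TRUE)
  check_number(body_length_mm, "body_length_mm", min = 0, strict_min = TRUE)
  structure(list(gate_body_lengths = gate_body_lengths, max_gap = max_gap,
                 body_length_mm = body_length_mm), class = "link_params")
}

#' Link per-frame detections into identity-resolved trajectories
#'
#' Frame-to-frame assignment minimizes total squared displacement between
#' each track's last known position and the new detections (optimal bipartite
#' assignment), subject to a hard displacement gate. Unmatched tracks coast;
#' when re-acquired within `max_gap` frames the gap is filled by linear
#' interpolation (flag `interpolated`), longer gaps stay `missing`. Surplus
#' detections are dropped as spurious.
#'
#' @param detections a `detection_set` (list of per-frame data.frames from
#'   [detect_sequence()]), or a plain list of such data.frames.
#' @param n_expected number of flies in the arena.
#' @param fps frames per second (default: from the detection set).
#' @param arena an [arena_spec()] (default: from the detection set); used
#'   for the pixel gate.
#' @param params a [link_params()] object.
#' @return A [trajectory_set()] in pixel units with per-sample flags.
#' @export
link_trajectories <- function(detections, n_expected, fps = NULL, arena = NULL,
                              params = link_params()) {
  if (is.null(fps)) fps <- attr(detections, "fps")
  if (is.null(arena)) arena <- attr(detections, "arena")
  validate_arena(arena)
  check_number(n_expected, "n_expected", min = 1, integer = TRUE)
  n <- as.integer(n_expected)
  T_ <- length(detections)
  gate_px <- params$gate_body_lengths * params$body_length_mm * arena$px_per_mm
  gate2 <- gate_px^2

  # initialization: first frame within max_gap + 1 holding >= n detections
  start <- NA_integer_
  for (t in seq_len(min(params$max_gap + 1L, T_))) {
    if (nrow(detections[[t]]) >= n) { start <- t; break }
  }
  if (is.na(start))
    snb_stop("snb_track_error",
             "tracking initialization failed: fewer than %d detections in each of the first %d frames",
             n, min(params$max_gap + 1L, T_))

  X <- matrix(NA_real_, T_, n); Y <- matrix(NA_real_, T_, n)
  FL <- matrix(FLAG_MISSING, T_, n)
  d0 <- detections[[start]]
  ord <- order(-d0$area_px, seq_len(nrow(d0)))[seq_len(n)]  # largest blobs first
  X[start, ] <- d0$x_px[ord]; Y[start, ] <- d0$y_px[ord]
  FL[start, ] <- FLAG_OBSERVED
  last_x <- X[start, ]; last_y <- Y[start, ]
  last_t <- rep(start, n)

  if (start < T_) for (t in (start + 1L):T_) {
    det <- detections[[t]]
    m <- nrow(det)
    if (m > 0L) {
      cost <- outer(last_x, det$x_px, "-")^2 + outer(last_y, det$y_px, "-")^2
      cost[cost > gate2] <- 1e12
      match <- lap_match(cost, unmatched_cost = gate2 + 1)
    } else match <- rep(NA_integer_, n)
    hit <- which(!is.na(match))
    for (i in hit) {
      j <- match[i]
      X[t, i] <- det$x_px[j]; Y[t, i] <- det$y_px[j]
      FL[t, i] <- FLAG_OBSERVED
      gap <- t - last_t[i] - 1L
      if (gap > 0L && gap <= params$max_gap) {
        tt <- (last_t[i] + 1L):(t - 1L)
        w <- (tt - last_t[i]) / (t - last_t[i])
        X[tt, i] <- last_x[i] + w * (X[t, i] - last_x[i])
        Y[tt, i] <- last_y[i] + w * (Y[t, i] - last_y[i])
        FL[tt, i] <- FLAG_INTERPOLATED
      }
      last_x[i] <- X[t, i]; last_y[i] <- Y[t, i]; last_t[i] <- t
    }
  }
  trajectory_set(X, Y, fps = fps, flag = FL, units = "px", arena = arena,
                 provenance = list(source = "link_trajectories",
                                   n_expected = n,
                                   gate_px = gate_px,
                                   max_gap = params$max_gap))
}

#' Render, detect and link a synthetic recording end to end
#'
#' Convenience wrapper used for tracker validation: renders a simulated
#' trajectory chunk by chunk (bounding memory), detects flies in every frame,
#' links identities and calibrates back to mm.
#'
#' @param traj ground-truth [trajectory_set()] in mm.
#' @param render a [render_params()] object.
#' @param detect a [detect_params()] object.
#' @param link a [link_params()] object.
#' @param chunk_size frames rendered per chunk.
#' @return List with `traj` (tracked, mm), `arena`, and `detections_per_frame`
#'   (integer vector).
#' @export
render_and_track <- function(traj, render = render_params(),
                             detect = detect_params(), link = link_params(),
                             chunk_size = 200L) {
  stopifnot(inherits(traj, "trajectory_set"))
  T_ <- n_frames(traj)
  dets <- vector("list", T_)
  arena <- NULL
  interior <- NULL
  for (lo in seq(1L, T_, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, T_)
    fs <- render_frames(traj, render, frames = lo:hi)
    if (is.null(arena)) {
      arena <- fs$arena
      interior <- arena_interior_mask(dim(fs$frames[[1L]]), arena,
                                      detect$mask_margin_px)
    }
    for (k in seq_along(fs$frames))
      dets[[lo + k - 1L]] <- detect_flies(fs$frames[[k]], arena, detect, interior)
  }
  dets <- structure(dets, class = "detection_set", arena = arena, fps = traj$fps)
  linked <- link_trajectories(dets, n_expected = n_flies(traj), params = link)
  list(traj = calibrate(linked, arena), arena = arena,
       detections_per_frame = vapply(dets, nrow, integer(1)))
}

#' Compare tracked trajectories against ground truth
#'
#' Finds the global track-to-truth permutation minimizing summed mean
#' distance (optimal assignment), then reports position error and identity
#' swaps: a sample counts as swapped when its nearest ground-truth fly in
#' that frame is not its globally assigned one.
#'
#' @param est,truth `trajectory_set`s in mm with equal fly counts.
#' @param px_per_mm optional pixel pitch to also report the RMSE in pixels.
#' @return List: `perm` (truth index for each track), `rmse_mm`, `rmse_px`,
#'   `swaps` (sample count), `n_valid` (samples compared).
#' @export
evaluate_tracking <- function(est, truth, px_per_mm = NULL) {
  stopifnot(inherits(est, "trajectory_set"), inherits(truth, "trajectory_set"))
  n <- n_flies(est)
  if (n != n_flies(truth) || n_frames(est) != n_frames(truth))
    stop_param("est/truth", "trajectory sets must have identical dimensions")
  ve <- valid_mask(est); vt <- valid_mask(truth)
  mean_d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- ve[, i] & vt[, j]
    mean_d[i, j] <- if (any(ok))
      mean(sqrt((est$x[ok, i] - truth$x[ok, j])^2 +
                (est$y[ok, i] - truth$y[ok, j])^2)) else Inf
  }
  mean_d[!is.finite(mean_d)] <- 1e9
  perm <- solve_lap(mean_d)
  sq <- 0; nv <- 0L; swaps <- 0L
  for (i in seq_len(n)) {
    j <- perm[i]
    ok <- which(ve[, i] & vt[, j])
    if (!length(ok)) next
    dx2 <- (est$x[ok, i] - truth$x[ok, j])^2 + (est$y[ok, i] - truth$y[ok, j])^2
    sq <- sq + sum(dx2); nv <- nv + length(ok)
    # nearest truth fly per sample
    dall <- sapply(seq_len(n), function(jj)
      (est$x[ok, i] - truth$x[ok, jj])^2 + (est$y[ok, i] - truth$y[ok, jj])^2)
    dall <- matrix(dall, nrow = length(ok))
    swaps <- swaps + sum(max.col(-dall, ties.method = "first") != j)
  }
  rmse <- sqrt(sq / max(nv, 1L))
  list(perm = perm, rmse_mm = rmse,
       rmse_px = if (is.null(px_per_mm)) NA_real_ else rmse * px_per_mm,
       swaps = swaps, n_valid = nv)
}
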