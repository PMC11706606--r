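#' Trajectory set container
#'
#' The central exchange object of the pipeline: per-frame, per-fly planar
#' positions on a common time base. Coordinates are in arena-centered
#' millimetres after [calibrate()] (image convention: x rightward, y downward)
#' or in raw image pixels straight out of [link_trajectories()]. Every sample
#' carries a flag: `"observed"` (detected/simulated), `"interpolated"`
#' (gap-filled) or `"missing"`.
#'
#' @param x,y numeric `T x n_flies` matrices of coordinates (frames in rows,
#'   flies in columns). `NA` allowed only where `flag` is `"missing"`.
#' @param fps frames per second (> 0).
#' @param flag integer `T x n_flies` matrix of per-sample flags (0 observed,
#'   1 interpolated, 2 missing), or `NULL` for all-observed.
#' @param units `"mm"` or `"px"`.
#' @param arena optional [arena_spec()] describing the recording geometry.
#' @param provenance named list recording how the object was produced
#'   (source file, simulation parameters, seed, ...).
#' @return An object of class `trajectory_set` with fields `x`, `y`, `flag`,
#'   `fps`, `times` (seconds, starting at 0), `units`, `arena`, `provenance`.
#' @export
trajectory_set <- function(x, y, fps, flag = NULL, units = c("mm", "px"),
                           arena = NULL, provenance = list()) {
  units <- match.arg(units)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop_param("x/y", "coordinate matrices must have equal dimensions")
  if (nrow(x) < 1L || ncol(x) < 1L) stop_param("x/y", "need at least one frame and one fly")
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  if (is.null(flag)) flag <- matrix(FLAG_OBSERVED, nrow(x), ncol(x))
  flag <- matrix(as.integer(flag), nrow(x), ncol(x))
  if (!all(flag %in% c(FLAG_OBSERVED, FLAG_INTERPOLATED, FLAG_MISSING)))
    stop_param("flag", "flags must be 0 (observed), 1 (interpolated) or 2 (missing)")
  bad <- (is.na(x) | is.na(y)) & flag != FLAG_MISSING
  if (any(bad)) stop_param("x/y", "NA coordinates only allowed for missing samples")
  structure(list(
    x = x, y = y, flag = flag, fps = fps,
    times = (seq_len(nrow(x)) - 1L) / fps,
    units = units, arena = arena, provenance = provenance
  ), class = "trajectory_set")
}

n_flies <- function(traj) ncol(traj$x)
n_frames <- function(traj) nrow(traj$x)

# samples usable as positions: observed or interpolated
valid_mask <- function(traj) traj$flag != FLAG_MISSING & !is.na(traj$x) & !is.na(traj$y)

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d flies x %d frames @ %g fps (%.1f s), units: %s\n",
              n_flies(x), n_frames(x), x$fps, n_frames(x) / x$fps, x$units))
  vf <- mean(valid_mask(x))
  cat(sprintf("  valid samples: %.1f%%; arena: %s\n", 100 * vf,
              if (is.null(x$arena)) "none" else
                sprintf("%.1f mm circle", x$arena$diameter_mm)))
  invisible(x)
}

#' Convert pixel trajectories to arena-centered millimetres
#'
#' Translates coordinates to the arena center and divides by the pixel pitch
#' (`px_per_mm`). The image y orientation (downward) is preserved so pixel
#' and mm frames differ only by scale and offset; flags are untouched.
#'
#' @param traj a `trajectory_set` in pixel units.
#' @param arena an [arena_spec()].
#' @return A `trajectory_set` in mm, with `arena` attached.
#' @seealso [decalibrate()] for the inverse map.
#' @export
calibrate <- function(traj, arena) {
  stopifnot(inherits(traj, "trajectory_set"))
  validate_arena(arena)
  if (traj$units != "px") stop_param("traj", "calibrate() expects pixel-unit trajectories")
  out <- traj
  out$x <- (traj$x - arena$center_px[1L]) / arena$px_per_mm
  out$y <- (traj$y - arena$center_px[2L]) / arena$px_per_mm
  out$units <- "mm"
  out$arena <- arena
  out
}

#' Convert mm trajectories back to image pixels
#'
#' Exact inverse of [calibrate()] for the same `arena_spec`.
#'
#' @inheritParams calibrate
#' @export
decalibrate <- function(traj, arena = traj$arena) {
  stopifnot(inherits(traj, "trajectory_set"))
  validate_arena(arena)
  if (traj$units != "mm") stop_param("traj", "decalibrate() expects mm-unit trajectories")
  out <- traj
  out$x <- traj$x * arena$px_per_mm + arena$center_px[1L]
  out$y <- traj$y * arena$px_per_mm + arena$center_px[2L]
  out$units <- "px"
  out$arena <- arena
  out
}

#' Plot fly trajectories
#'
#' Draws each fly's path inside the arena outline (mm units, y axis downward
#' to match the image convention).
#'
#' @param x a `trajectory_set` in mm.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_set <- function(x, ...) {
  stopifnot(x$units == "mm")
  r <- if (!is.null(x$arena)) x$arena$diameter_mm / 2 else max(abs(c(x$x, x$y)), na.rm = TRUE)
  plot(NA, xlim = c(-r, r), ylim = c(r, -r), asp = 1,
       xlab = "x (mm)", ylab = "y (mm)", ...)
  th <- seq(0, 2 * pi, length.out = 181)
  lines(r * cos(th), r * sin(th), col = "grey60")
  cols <- grDevices::hcl.colors(n_flies(x), "Dark 3")
  for (i in seq_len(n_flies(x))) lines(x$x[, i], x$y[, i], col = cols[i], lwd = 0.6)
  invisible(x)
}
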