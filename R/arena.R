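#' Circular arena geometry
#'
#' Describes the recording arena: its circle in image pixels and its physical
#' diameter, from which the pixel pitch `px_per_mm = 2 * radius_px /
#' diameter_mm` follows. The pixel geometry may be omitted for trajectories
#' that were never in pixel space (simulated mm coordinates).
#'
#' @param center_px numeric length-2, circle center `(x, y)` in pixels
#'   (0-based image convention: x rightward, y downward, pixel centers at
#'   integer coordinates), or `NULL`.
#' @param radius_px circle radius in pixels (> 0), or `NULL`.
#' @param diameter_mm physical arena diameter in mm (default 55, the 5.5 cm
#'   dish; the large-arena variant is 85).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(center_px = NULL, radius_px = NULL, diameter_mm = 55) {
  check_number(diameter_mm, "diameter_mm", min = 0, strict_min = TRUE)
  spec <- structure(list(center_px = center_px, radius_px = radius_px,
                         diameter_mm = diameter_mm,
                         px_per_mm = NULL), class = "arena_spec")
  if (!is.null(radius_px)) {
    check_number(radius_px, "radius_px", min = 0, strict_min = TRUE)
    if (is.null(center_px) || length(center_px) != 2L || !all(is.finite(center_px)))
      stop_param("center_px", "must be a finite (x, y) pair when radius_px is given")
    spec$px_per_mm <- 2 * radius_px / diameter_mm
  }
  spec
}

validate_arena <- function(arena) {
  if (!inherits(arena, "arena_spec")) stop_param("arena", "must be an arena_spec")
  if (is.null(arena$radius_px) || is.null(arena$px_per_mm))
    stop_param("arena", "pixel geometry (center_px, radius_px) is required here")
  invisible(arena)
}

#' @export
print.arena_spec <- function(x, ...) {
  if (is.null(x$radius_px)) {
    cat(sprintf("<arena_spec> %.1f mm circle (no pixel geometry)\n", x$diameter_mm))
  } else {
    cat(sprintf("<arena_spec> center (%.2f, %.2f) px, radius %.2f px, %.1f mm (%.3f px/mm)\n",
                x$center_px[1L], x$center_px[2L], x$radius_px, x$diameter_mm, x$px_per_mm))
  }
  invisible(x)
}

#' Fit the arena circle in a frame
#'
#' Segments the bright arena interior (Otsu threshold), keeps the largest
#' connected component, and fits a circle to it: center = component centroid,
#' radius from the component area (`sqrt(area / pi)`), which is robust to the
#' dark fly blobs sitting inside the arena. A circularity check (area radius
#' vs. bounding-box radius) rejects frames without a dominant circular arena.
#' If an `arena_spec` is already configured, pass it through instead of
#' fitting.
#'
#' @param frame numeric matrix of 8-bit gray values (rows = y, cols = x).
#' @param diameter_mm physical arena diameter used for calibration.
#' @return An [arena_spec()] with pixel geometry and `px_per_mm`.
#' @export
fit_arena <- function(frame, diameter_mm = 55) {
  frame <- as.matrix(frame)
  if (diff(range(frame)) < 1)
    snb_stop("snb_calibration_error", "arena calibration failed: frame has no contrast")
  thr <- EBImage::otsu(EBImage::Image(frame / 255), range = c(0, 1))
  mask <- frame / 255 > thr
  lab <- EBImage::bwlabel(EBImage::fillHull(mask))  # flies punch holes; fill them
  if (max(lab) < 1L)
    snb_stop("snb_calibration_error", "arena calibration failed: no bright region found")
  areas <- tabulate(lab[lab > 0L])
  big <- which.max(areas)
  idx <- which(lab == big, arr.ind = TRUE)
  # 0-based image coordinates: x = col - 1, y = row - 1
  cx <- mean(idx[, 2L]) - 1; cy <- mean(idx[, 1L]) - 1
  r_area <- sqrt(areas[big] / pi)
  r_bb <- (max(diff(range(idx[, 1L])), diff(range(idx[, 2L]))) + 1) / 2
  if (abs(r_area - r_bb) > 0.05 * r_bb + 2)
    snb_stop("snb_calibration_error",
             "arena calibration failed: dominant region is not circular (area radius %.1f px vs extent %.1f px)",
             r_area, r_bb)
  if (cx - r_area < -1 || cy - r_area < -1 ||
      cx + r_area > ncol(frame) || cy + r_area > nrow(frame))
    snb_stop("snb_calibration_error", "arena calibration failed: fitted circle exceeds frame bounds")
  arena_spec(center_px = c(cx, cy), radius_px = r_area, diameter_mm = diameter_mm)
}
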