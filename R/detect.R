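#' Fly detection parameters
#'
#' Dark blobs are segmented by intensity threshold inside the arena circle,
#' labeled as connected components, filtered by area bounds scaled from the
#' expected body size, and located by intensity-weighted subpixel centroids.
#'
#' @param mode `"adaptive"` (threshold midway between the interior background
#'   median and the darkest interior pixel; requires at least
#'   `min_contrast` gray levels of contrast, otherwise no detections) or
#'   `"fixed"` (use `threshold`).
#' @param threshold fixed gray-level threshold (pixels strictly below are
#'   foreground); required when `mode = "fixed"`.
#' @param body_length_mm expected fly body length; with the arena pixel
#'   pitch this sets the expected blob area `pi * (body_length_mm/2 *
#'   px_per_mm)^2`.
#' @param area_factor length-2 multiplicative bounds on blob area relative
#'   to the expected area.
#' @param min_contrast adaptive mode: minimum background-to-darkest contrast
#'   (gray levels) for any detection to be attempted.
#' @param mask_margin_px arena mask is eroded by this margin so the arena
#'   edge gradient is never segmented.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(mode = c("adaptive", "fixed"), threshold = NULL,
                          body_length_mm = 2.5, area_factor = c(0.15, 5),
                          min_contrast = 20, mask_margin_px = 2) {
  mode <- match.arg(mode)
  if (mode == "fixed") check_number(threshold, "threshold", min = 0, max = 255)
  check_number(body_length_mm, "body_length_mm", min = 0, strict_min = TRUE)
  if (length(area_factor) != 2L || area_factor[1L] >= area_factor[2L])
    stop_param("area_factor", "must be increasing length-2 bounds")
  structure(list(mode = mode, threshold = threshold,
                 body_length_mm = body_length_mm, area_factor = area_factor,
                 min_contrast = min_contrast, mask_margin_px = mask_margin_px),
            class = "detect_params")
}

arena_interior_mask <- function(dim_hw, arena, margin) {
  xs <- seq_len(dim_hw[2L]) - 1L; ys <- seq_len(dim_hw[1L]) - 1L
  d2 <- outer((ys - arena$center_px[2L])^2, (xs - arena$center_px[1L])^2, "+")
  d2 <= (arena$radius_px - margin)^2
}

#' Detect flies in one frame
#'
#' @param frame numeric/integer matrix of 8-bit gray values.
#' @param arena an [arena_spec()] with pixel geometry.
#' @param params a [detect_params()] object.
#' @param interior optional precomputed logical mask (from
#'   [detect_sequence()]) to avoid recomputing it per frame.
#' @return A data.frame with one row per detection: `x_px`, `y_px`
#'   (subpixel, 0-based), `area_px`, `mean_intensity`. Zero rows is valid.
#' @export
detect_flies <- function(frame, arena, params = detect_params(), interior = NULL) {
  validate_arena(arena)
  frame <- as.matrix(frame)
  if (is.null(interior))
    interior <- arena_interior_mask(dim(frame), arena, params$mask_margin_px)
  vals <- frame[interior]
  bg <- median(vals)
  if (params$mode == "fixed") {
    thr <- params$threshold
  } else {
    darkest <- min(vals)
    if (bg - darkest < params$min_contrast)
      return(data.frame(x_px = numeric(0), y_px = numeric(0),
                        area_px = numeric(0), mean_intensity = numeric(0)))
    thr <- (bg + darkest) / 2
  }
  fg <- frame < thr & interior
  if (!any(fg))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), mean_intensity = numeric(0)))
  lab <- EBImage::bwlabel(fg)
  area_exp <- pi * (params$body_length_mm / 2 * arena$px_per_mm)^2
  lo <- params$area_factor[1L] * area_exp
  hi <- params$area_factor[2L] * area_exp
  npx <- tabulate(lab[lab > 0L])
  keep <- which(npx >= lo & npx <= hi)
  if (!length(keep))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), mean_intensity = numeric(0)))
  idx <- which(lab > 0L, arr.ind = TRUE)
  comp <- lab[lab > 0L]
  inten <- frame[lab > 0L]
  w <- pmax(bg - inten, 0)                      # darkness weight for centroid
  res <- lapply(keep, function(ci) {
    sel <- comp == ci
    ws <- w[sel]; tot <- sum(ws)
    if (tot <= 0) { ws <- rep(1, sum(sel)); tot <- sum(ws) }
    c(x = sum((idx[sel, 2L] - 1) * ws) / tot,
      y = sum((idx[sel, 1L] - 1) * ws) / tot,
      area = npx[ci], mi = mean(inten[sel]))
  })
  m <- do.call(rbind, res)
  data.frame(x_px = m[, "x"], y_px = m[, "y"],
             area_px = m[, "area"], mean_intensity = m[, "mi"])
}

#' Detect flies in every frame of a sequence
#'
#' @param fs a `frame_sequence` (see [render_frames()] / [read_frames()]).
#' @param arena an [arena_spec()]; defaults to the sequence's own (ground
#'   truth or sidecar), otherwise fit from the first frame.
#' @param params a [detect_params()] object.
#' @return A list of per-frame detection data.frames (class
#'   `detection_set`), with the arena attached as an attribute.
#' @export
detect_sequence <- function(fs, arena = NULL, params = detect_params()) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (is.null(arena)) arena <- fs$arena
  if (is.null(arena)) arena <- fit_arena(fs$frames[[1L]])
  interior <- arena_interior_mask(dim(fs$frames[[1L]]), arena, params$mask_margin_px)
  out <- lapply(fs$frames, detect_flies, arena = arena, params = params,
                interior = interior)
  structure(out, class = "detection_set", arena = arena, fps = fs$fps)
}
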