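#' Rendering parameters for synthetic arena video
#'
#' Flies are drawn as anti-aliased dark disks on a light agar background,
#' inside a bright arena circle surrounded by a darker margin (so the arena
#' can be re-fit from the frames). Optional i.i.d. Gaussian pixel noise
#' emulates sensor noise.
#'
#' @param px_per_mm pixel pitch (> 0). Default 5 gives a ~275 px arena for
#'   the 55 mm dish.
#' @param background_gray agar background intensity, 0-255.
#' @param fly_gray fly body intensity; must be darker than the background.
#' @param outside_gray intensity outside the arena circle.
#' @param noise_sd SD of additive Gaussian noise in gray levels (0 = clean).
#' @param fly_radius_mm radius of the rendered fly disk in mm.
#' @return A validated list of class `render_params`.
#' @export
render_params <- function(px_per_mm = 5, background_gray = 200, fly_gray = 60,
                          outside_gray = 40, noise_sd = 3, fly_radius_mm = 1.1) {
  check_number(px_per_mm, "px_per_mm", min = 0, strict_min = TRUE)
  check_number(background_gray, "background_gray", min = 0, max = 255)
  check_number(fly_gray, "fly_gray", min = 0, max = 255)
  check_number(outside_gray, "outside_gray", min = 0, max = 255)
  if (fly_gray >= background_gray)
    stop_param("fly_gray", "flies must be darker than the background")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(fly_radius_mm, "fly_radius_mm", min = 0, strict_min = TRUE)
  structure(list(px_per_mm = px_per_mm, background_gray = background_gray,
                 fly_gray = fly_gray, outside_gray = outside_gray,
                 noise_sd = noise_sd, fly_radius_mm = fly_radius_mm),
            class = "render_params")
}

render_geometry <- function(arena_diameter_mm, render) {
  ppm <- render$px_per_mm
  r_px <- arena_diameter_mm / 2 * ppm
  pad <- 8
  half <- ceiling(r_px + pad)
  wh <- 2L * as.integer(half) + 1L           # odd size, integer center pixel
  list(width = wh, height = wh, center_px = c(half, half), radius_px = r_px)
}

# anti-aliased disk coverage on the pixel grid; returns canvas with the disk
# alpha-composited at intensity `value`
draw_disk <- function(canvas, cx, cy, r, value) {
  x0 <- floor(cx - r - 1); x1 <- ceiling(cx + r + 1)
  y0 <- floor(cy - r - 1); y1 <- ceiling(cy + r + 1)
  if (x0 < 0 || y0 < 0 || x1 > ncol(canvas) - 1L || y1 > nrow(canvas) - 1L)
    snb_stop("snb_render_error",
             "fly disk at (%.1f, %.1f) px extends beyond the canvas", cx, cy)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  rows <- ys + 1L; cols <- xs + 1L
  canvas[rows, cols] <- canvas[rows, cols] * (1 - cov) + value * cov
  canvas
}

base_canvas <- function(geom, render) {
  xs <- seq_len(geom$width) - 1L; ys <- seq_len(geom$height) - 1L
  d <- sqrt(outer((ys - geom$center_px[2L])^2, (xs - geom$center_px[1L])^2, "+"))
  cov <- pmin(pmax(geom$radius_px + 0.5 - d, 0), 1)
  render$outside_gray * (1 - cov) + render$background_gray * cov
}

#' Render trajectories into synthetic video frames
#'
#' One 8-bit grayscale frame per trajectory frame; each fly is an
#' anti-aliased dark disk at its projected pixel position. Noise, when
#' enabled, is seeded per frame index so rendering in chunks reproduces the
#' full-sequence output exactly.
#'
#' @param traj a [trajectory_set()] in mm with an arena diameter.
#' @param render a [render_params()] object.
#' @param frames integer vector of 1-based frame indices to render
#'   (default: all).
#' @param noise_seed base seed for the per-frame noise streams.
#' @return An object of class `frame_sequence`: list with `frames` (list of
#'   integer matrices), `frame_idx`, `fps`, `arena` (ground-truth
#'   [arena_spec()] of the rendered circle) and `render`.
#' @export
render_frames <- function(traj, render = render_params(), frames = NULL,
                          noise_seed = 0L) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (traj$units != "mm") stop_param("traj", "render_frames() expects mm-unit trajectories")
  if (is.null(traj$arena)) stop_param("traj", "trajectory has no arena geometry")
  dia <- traj$arena$diameter_mm
  geom <- render_geometry(dia, render)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  base <- base_canvas(geom, render)
  ppm <- render$px_per_mm
  r_fly <- render$fly_radius_mm * ppm
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    canvas <- base
    for (i in seq_len(n_flies(traj))) {
      if (traj$flag[t, i] == FLAG_MISSING) next
      cx <- geom$center_px[1L] + traj$x[t, i] * ppm
      cy <- geom$center_px[2L] + traj$y[t, i] * ppm
      canvas <- draw_disk(canvas, cx, cy, r_fly, render$fly_gray)
    }
    if (render$noise_sd > 0) {
      canvas <- with_seed(noise_seed + t, {
        canvas + rnorm(length(canvas), 0, render$noise_sd)
      })
    }
    canvas <- round(pmin(pmax(canvas, 0), 255))
    storage.mode(canvas) <- "integer"
    out[[k]] <- canvas
  }
  structure(list(frames = out, frame_idx = frames, fps = traj$fps,
                 arena = arena_spec(center_px = geom$center_px,
                                    radius_px = geom$radius_px,
                                    diameter_mm = dia),
                 render = render),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames, %d x %d px @ %g fps\n",
              length(x$frames), d[2L], d[1L], x$fps))
  invisible(x)
}

#' Write frames as numbered PNG files
#'
#' Writes `frame_000001.png`, ... plus a `frames.yaml` sidecar holding fps,
#' the arena circle, pixel pitch and render parameters.
#'
#' @param fs a `frame_sequence`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(fs, dir) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(fs$frames)) {
    png::writePNG(fs$frames[[k]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", fs$frame_idx[k])))
  }
  meta <- list(fps = fs$fps,
               arena = list(center_px = as.numeric(fs$arena$center_px),
                            radius_px = fs$arena$radius_px,
                            diameter_mm = fs$arena$diameter_mm),
               render = unclass(fs$render))
  yaml::write_yaml(meta, file.path(dir, "frames.yaml"))
  invisible(dir)
}

#' Read a directory of numbered PNG frames
#'
#' @param dir directory written by [write_frames()] (or any directory of
#'   same-size grayscale PNGs plus an optional `frames.yaml` sidecar).
#' @param fps frames per second; overrides the sidecar if given.
#' @return A `frame_sequence`.
#' @export
read_frames <- function(dir, fps = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) snb_stop("snb_parse_error", "no PNG frames found in '%s'", dir)
  meta_path <- file.path(dir, "frames.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(fps)) fps <- meta$fps
  if (is.null(fps)) snb_stop("snb_parse_error", "fps not given and no frames.yaml sidecar")
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m <- round(m * 255); storage.mode(m) <- "integer"; m
  })
  arena <- if (!is.null(meta$arena))
    arena_spec(center_px = as.numeric(meta$arena$center_px),
               radius_px = meta$arena$radius_px,
               diameter_mm = meta$arena$diameter_mm) else NULL
  structure(list(frames = frames, frame_idx = seq_along(frames), fps = fps,
                 arena = arena, render = meta$render),
            class = "frame_sequence")
}
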