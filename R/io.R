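# Trajectory CSV schema, pipeline configuration, structured logging.

fmt_num <- function(x) {
  # round-trip-safe decimal representation (17 significant digits)
  out <- formatC(x, digits = 17, format = "g", width = 1)
  out[is.na(x)] <- ""
  out
}

#' Write trajectories as CSV (plus a metadata sidecar)
#'
#' Schema: columns `frame` (0-based), `time_s`, `fly_id` (0-based), `x_mm`,
#' `y_mm`, `flag` (`observed` / `interpolated` / `missing`); header row;
#' rows sorted by `(frame, fly_id)`; missing coordinates as empty fields.
#' Coordinates are written with 17 significant digits so write -> read is
#' lossless. A `<path>.yaml` sidecar records fps, fly count, units, arena
#' and provenance.
#'
#' @param traj a [trajectory_set()] in mm.
#' @param path output CSV path.
#' @param sidecar write the YAML sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (traj$units != "mm")
    stop_param("traj", "trajectory CSV schema is mm-based; calibrate() first")
  T_ <- n_frames(traj); n <- n_flies(traj)
  df <- data.frame(
    frame = rep(seq_len(T_) - 1L, each = n),
    time_s = fmt_num(rep(traj$times, each = n)),
    fly_id = rep(seq_len(n) - 1L, times = T_),
    x_mm = fmt_num(as.vector(t(traj$x))),
    y_mm = fmt_num(as.vector(t(traj$y))),
    flag = flag_to_chr(as.vector(t(traj$flag)))
  )
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(fps = traj$fps, n_flies = n, n_frames = T_, units = traj$units,
                 package_version = as.character(packageVersion("flysnb")))
    if (!is.null(traj$arena))
      meta$arena <- list(diameter_mm = traj$arena$diameter_mm,
                         center_px = if (!is.null(traj$arena$center_px))
                           as.numeric(traj$arena$center_px),
                         radius_px = traj$arena$radius_px)
    if (length(traj$provenance)) {
      meta$provenance <- rapply(traj$provenance, function(z)
        if (is.numeric(z) || is.character(z) || is.logical(z)) z else NULL,
        how = "replace")
    }
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

parse_stop <- function(row, col, fmt, ...) {
  snb_stop("snb_parse_error",
           paste0("trajectory CSV parse error at row %d, column '%s': ", fmt),
           row, col, ...)
}

#' Read a trajectory CSV
#'
#' Validates the schema written by [write_trajectories()]: mandatory header,
#' rows sorted by `(frame, fly_id)` and unique, a complete frame x fly grid,
#' known flag values, coordinates present unless the sample is `missing`
#' (empty coordinate fields force the flag to `missing`). Violations raise a
#' parse error naming the offending row and column.
#'
#' @param path CSV path.
#' @param fps frames per second; defaults to the `<path>.yaml` sidecar.
#' @param arena optional [arena_spec()]; defaults to the sidecar geometry.
#' @return A [trajectory_set()] in mm.
#' @export
read_trajectories <- function(path, fps = NULL, arena = NULL) {
  if (!file.exists(path)) snb_stop("snb_parse_error", "file not found: %s", path)
  need <- c("frame", "time_s", "fly_id", "x_mm", "y_mm", "flag")
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  miss <- setdiff(need, hdr)
  if (length(miss)) parse_stop(0L, miss[1L], "required column missing")
  df <- read.csv(path, colClasses = c(frame = "integer", time_s = "numeric",
                                      fly_id = "integer", x_mm = "numeric",
                                      y_mm = "numeric", flag = "character"),
                 na.strings = "")
  if (!nrow(df)) snb_stop("snb_parse_error", "empty trajectory file")

  key <- df$frame * (max(df$fly_id) + 1) + df$fly_id
  if (anyDuplicated(key)) {
    r <- which(duplicated(key))[1L]
    parse_stop(r, "frame", "duplicate (frame, fly_id) pair (%d, %d)",
               df$frame[r], df$fly_id[r])
  }
  if (is.unsorted(key)) {
    r <- which(diff(key) < 0)[1L] + 1L
    parse_stop(r, "frame", "rows not sorted by (frame, fly_id)")
  }
  flag <- chr_to_flag(df$flag)
  # empty coordinates => missing; observed/interpolated rows need coordinates
  bare <- is.na(df$x_mm) | is.na(df$y_mm)
  flag[bare] <- FLAG_MISSING
  frames <- sort(unique(df$frame)); flies <- sort(unique(df$fly_id))
  T_ <- length(frames); n <- length(flies)
  if (nrow(df) != T_ * n)
    snb_stop("snb_parse_error",
             "incomplete grid: %d rows but %d frames x %d flies", nrow(df), T_, n)
  if (!identical(frames, seq_len(T_) - 1L))
    snb_stop("snb_parse_error", "frame indices must be 0..T-1 without holes")

  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(fps)) fps <- meta$fps
  if (is.null(fps)) snb_stop("snb_parse_error", "fps not given and no sidecar found")
  if (is.null(arena) && !is.null(meta$arena))
    arena <- arena_spec(center_px = if (!is.null(meta$arena$center_px))
                          as.numeric(meta$arena$center_px),
                        radius_px = meta$arena$radius_px,
                        diameter_mm = meta$arena$diameter_mm)

  X <- matrix(df$x_mm, T_, n, byrow = TRUE)
  Y <- matrix(df$y_mm, T_, n, byrow = TRUE)
  FL <- matrix(flag, T_, n, byrow = TRUE)
  trajectory_set(X, Y, fps = fps, flag = FL, units = "mm", arena = arena,
                 provenance = list(source = path,
                                   sidecar = if (length(meta)) meta))
}

#' Default pipeline configuration
#'
#' The full parameter surface of the pipeline as one nested list; every run
#' resolves user values against these defaults and writes the resolved
#' configuration next to its outputs, which suffices to reproduce the run.
#'
#' @return Nested named list (sections `seed`, `simulate`, `render`,
#'   `detect`, `link`, `metrics`, `track`).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = c(unclass(sim_params()), list(regime = "none")),
    render = unclass(render_params()),
    detect = list(mode = "adaptive", threshold = NULL, body_length_mm = 2.5,
                  area_factor = c(0.15, 5), min_contrast = 20, mask_margin_px = 2),
    link = unclass(link_params()),
    metrics = list(sd_mode = "mean_pairwise", cv_estimator = "iqr_dispersion",
                   smooth_window = 1L),
    track = list(enabled = TRUE, input = "simulate", frames_dir = NULL,
                 trajectories_csv = NULL, chunk_size = 200L)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    snb_stop("snb_config_error", "unknown configuration key '%s%s'", path, unknown[1L])
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read and resolve a pipeline configuration file
#'
#' YAML with the sections of [default_config()]; unknown keys are rejected.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Resolved configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) snb_stop("snb_config_error", "configuration must be a mapping")
    cfg <- merge_config(cfg, user)
  }
  cfg
}

log_stage <- function(stage, ...) {
  kv <- c(...)
  msg <- if (length(kv))
    paste(sprintf("%s=%s", names(kv), as.character(kv)), collapse = " ") else ""
  message(sprintf("[flysnb] stage=%s %s", stage, msg))
}

#' Run the full pipeline from a configuration
#'
#' Executes the configured stages in order — simulate (or load
#' trajectories/frames), render + track, metrics — with structured logging
#' to stderr and all outputs plus the resolved configuration written under
#' `out_dir`. Deterministic: the same configuration and seed give
#' byte-identical CSV outputs.
#'
#' @param config a configuration list ([read_config()] result), or the path
#'   to a YAML configuration file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `truth` (simulated trajectory or `NULL`),
#'   `traj` (analyzed trajectory), `metrics` ([group_metrics()]), and the
#'   paths written.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (is.character(config)) read_config(config)
         else if (is.null(config)) default_config()
         else merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- list(config = file.path(out_dir, "config_resolved.yaml"))
  yaml::write_yaml(cfg, paths$config)

  truth <- NULL
  input <- cfg$track$input
  if (identical(input, "simulate")) {
    sp <- cfg$simulate
    regime <- sp$regime; sp$regime <- NULL
    params <- do.call(sim_params, sp)
    if (!identical(regime, "none"))
      params <- apply_overrides(params, behavior_regime(regime))
    if (is.null(params$seed) || !length(params$seed)) params <- apply_overrides(params, list(seed = cfg$seed))
    log_stage("simulate", n_flies = params$n_flies, duration_s = params$duration_s,
              regime = regime, seed = params$seed)
    truth <- simulate_group(params)
    paths$truth <- file.path(out_dir, "trajectories_truth.csv")
    write_trajectories(truth, paths$truth)
    source_traj <- truth
  } else if (identical(input, "trajectories")) {
    if (is.null(cfg$track$trajectories_csv))
      snb_stop("snb_pipeline_error", "stage=input: track.trajectories_csv not set")
    if (!file.exists(cfg$track$trajectories_csv))
      snb_stop("snb_pipeline_error", "stage=input: missing input path '%s'",
               cfg$track$trajectories_csv)
    log_stage("read", path = cfg$track$trajectories_csv)
    source_traj <- read_trajectories(cfg$track$trajectories_csv)
  } else if (identical(input, "frames")) {
    if (is.null(cfg$track$frames_dir) || !dir.exists(cfg$track$frames_dir))
      snb_stop("snb_pipeline_error", "stage=input: missing frames directory")
    log_stage("read_frames", dir = cfg$track$frames_dir)
    fs <- read_frames(cfg$track$frames_dir)
    arena <- if (!is.null(fs$arena)) fs$arena
             else fit_arena(fs$frames[[1L]], cfg$simulate$arena_diameter_mm)
    dp <- do.call(detect_params, cfg$detect)
    dets <- detect_sequence(fs, arena, dp)
    log_stage("detect", frames = length(dets),
              mean_detections = sprintf("%.2f", mean(vapply(dets, nrow, integer(1)))))
    lp <- link_params(gate_body_lengths = cfg$link$gate_body_lengths,
                      max_gap = cfg$link$max_gap,
                      body_length_mm = cfg$link$body_length_mm)
    source_traj <- calibrate(
      link_trajectories(dets, n_expected = cfg$simulate$n_flies, params = lp), arena)
  } else snb_stop("snb_config_error", "track.input must be simulate/trajectories/frames")

  if (isTRUE(cfg$track$enabled) && identical(input, "simulate")) {
    rp <- do.call(render_params, cfg$render)
    dp <- do.call(detect_params, cfg$detect)
    lp <- link_params(gate_body_lengths = cfg$link$gate_body_lengths,
                      max_gap = cfg$link$max_gap,
                      body_length_mm = cfg$link$body_length_mm)
    log_stage("render_track", px_per_mm = rp$px_per_mm, noise_sd = rp$noise_sd)
    tr <- render_and_track(truth, rp, dp, lp,
                           chunk_size = cfg$track$chunk_size)
    traj <- tr$traj
  } else traj <- source_traj

  paths$traj <- file.path(out_dir, "trajectories.csv")
  write_trajectories(traj, paths$traj)
  gm <- group_metrics(traj, sd_mode = cfg$metrics$sd_mode,
                      cv_estimator = cfg$metrics$cv_estimator,
                      smooth_window = cfg$metrics$smooth_window)
  paths$metrics <- file.path(out_dir, "metrics.csv")
  mdf <- as.data.frame(gm)
  mdf[] <- lapply(mdf, function(c_) if (is.numeric(c_)) fmt_num(c_) else c_)
  write.table(mdf, paths$metrics, sep = ",", row.names = FALSE, quote = FALSE)
  log_stage("metrics", sd_overall = sprintf("%.4f", gm$sd_overall),
            walking_speed = sprintf("%.4f", gm$walking_speed),
            elapsed_s = sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(truth = truth, traj = traj, metrics = gm, paths = paths))
}
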