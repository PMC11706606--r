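#' Simulation parameters for the agent-based fly group model
#'
#' Defaults reproduce the study conditions: 16 male flies freely moving for
#' 10 min in a 5.5 cm circular agar arena. The dynamics parameters control a
#' persistent random walk with social attraction, hard-core repulsion and a
#' per-minute multiplicative speed decay (see the methods vignette).
#'
#' @param n_flies number of flies (>= 1).
#' @param duration_s recording duration in seconds.
#' @param fps frames per second of the simulated recording.
#' @param arena_diameter_mm arena diameter in mm (must exceed two body lengths).
#' @param body_length_mm fly body length in mm; sets the wall margin and the
#'   default displacement gate of the tracker.
#' @param base_speed_mm_s initial walking speed in mm/s.
#' @param speed_decay_per_min fraction of speed lost per minute, in \[0, 1\];
#'   speed at time t is `base_speed_mm_s * (1 - speed_decay_per_min)^(t/60)`.
#' @param attraction unitless strength (>= 0) of turning toward the centroid
#'   of the other flies; 0 gives a pure persistent random walk.
#' @param repulsion_radius_mm hard-core separation: flies closer than this are
#'   pushed apart after each step.
#' @param heading_noise_sd_rad heading diffusion, SD of the heading increment
#'   per square-root second (rad/sqrt(s)).
#' @param seed integer RNG seed; a fixed seed gives bit-identical trajectories.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_flies = 16, duration_s = 600, fps = 30,
                       arena_diameter_mm = 55, body_length_mm = 2.5,
                       base_speed_mm_s = 8, speed_decay_per_min = 0.05,
                       attraction = 0, repulsion_radius_mm = 3,
                       heading_noise_sd_rad = 1.2, seed = 1L) {
  p <- structure(list(
    n_flies = n_flies, duration_s = duration_s, fps = fps,
    arena_diameter_mm = arena_diameter_mm, body_length_mm = body_length_mm,
    base_speed_mm_s = base_speed_mm_s, speed_decay_per_min = speed_decay_per_min,
    attraction = attraction, repulsion_radius_mm = repulsion_radius_mm,
    heading_noise_sd_rad = heading_noise_sd_rad, seed = seed
  ), class = "sim_params")
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  check_number(p$n_flies, "n_flies", min = 1, integer = TRUE)
  check_number(p$duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(p$fps, "fps", min = 0, strict_min = TRUE)
  check_number(p$arena_diameter_mm, "arena_diameter_mm", min = 0, strict_min = TRUE)
  check_number(p$body_length_mm, "body_length_mm", min = 0, strict_min = TRUE)
  if (p$arena_diameter_mm <= 2 * p$body_length_mm)
    stop_param("arena_diameter_mm", "must exceed 2 * body_length_mm")
  check_number(p$base_speed_mm_s, "base_speed_mm_s", min = 0)
  check_number(p$speed_decay_per_min, "speed_decay_per_min", min = 0, max = 1)
  check_number(p$attraction, "attraction", min = 0)
  check_number(p$repulsion_radius_mm, "repulsion_radius_mm", min = 0)
  check_number(p$heading_noise_sd_rad, "heading_noise_sd_rad", min = 0)
  if (!is.null(p$seed)) check_number(p$seed, "seed", integer = TRUE)
  invisible(p)
}

#' Behavioral regime presets
#'
#' Two documented parameter presets reproducing the qualitative phenotypes of
#' short- and long-SD fly lines: `short_sd` clusters (strong attraction, fast
#' speed decay, so SD and walking speed fall over the recording); `long_sd`
#' disperses (no attraction, slow decay, sustained exploration).
#'
#' @param label `"short_sd"` or `"long_sd"`.
#' @return Named list of `sim_params` overrides.
#' @export
behavior_regime <- function(label = c("short_sd", "long_sd")) {
  label <- match.arg(label)
  switch(label,
    short_sd = list(attraction = 1.5, speed_decay_per_min = 0.35),
    long_sd  = list(attraction = 0, speed_decay_per_min = 0.05)
  )
}

#' Apply overrides to simulation parameters
#'
#' @param params a [sim_params()] object.
#' @param overrides named list of fields to replace (e.g. a regime preset).
#' @return Validated `sim_params`.
#' @export
apply_overrides <- function(params, overrides) {
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) stop_param(unknown[1L], "unknown sim_params field")
  p <- structure(modifyList(unclass(params), overrides), class = "sim_params")
  validate_sim_params(p)
}

#' Injury condition overrides
#'
#' A labeled convenience for plasticity experiments, not a mechanism claim:
#' physical injury makes group-reared ("socialized") flies slow down and
#' cluster (attraction + 4, base speed x 0.6); developmentally isolated flies
#' are insensitive (no change).
#'
#' @param socialized logical; was the fly group-reared?
#' @return Named list of overrides (possibly empty).
#' @export
injury_overrides <- function(socialized) {
  if (isTRUE(socialized)) list(attraction_add = 4, speed_mult = 0.6) else list()
}

apply_injury <- function(params, socialized) {
  ov <- injury_overrides(socialized)
  if (!length(ov)) return(params)
  apply_overrides(params, list(
    attraction = params$attraction + ov$attraction_add,
    base_speed_mm_s = params$base_speed_mm_s * ov$speed_mult
  ))
}

#' Simulate a group recording
#'
#' Agent-based model of flies in a circular arena. Each fly performs a
#' persistent random walk; per step (dt = 1/fps) the heading is steered
#' toward the centroid of the other flies with weight `attraction * dt`,
#' perturbed by Gaussian noise, and the fly advances at the decayed speed.
#' Pairs closer than `repulsion_radius_mm` are pushed apart (hard core), and
#' the wall reflects both the offending radial displacement and the heading,
#' so positions never leave the arena disk.
#'
#' @param params a [sim_params()] object.
#' @return A [trajectory_set()] in mm, arena-centered, `duration_s * fps`
#'   frames, all samples observed; deterministic for a fixed `seed`.
#' @examples
#' traj <- simulate_group(sim_params(n_flies = 4, duration_s = 5, seed = 7))
#' traj
#' @export
simulate_group <- function(params) {
  validate_sim_params(params)
  n <- as.integer(params$n_flies)
  T_ <- max(1L, as.integer(round(params$duration_s * params$fps)))
  dt <- 1 / params$fps
  R <- params$arena_diameter_mm / 2
  r_body <- params$body_length_mm / 2
  Rw <- R - r_body                       # wall offset keeps bodies inside
  r_rep <- params$repulsion_radius_mm
  noise_sd <- params$heading_noise_sd_rad * sqrt(dt)
  att_w <- params$attraction * dt
  decay <- 1 - params$speed_decay_per_min

  X <- matrix(NA_real_, T_, n)
  Y <- matrix(NA_real_, T_, n)

  with_seed(params$seed, {
    # sequential placement with soft minimum-separation rejection
    px <- numeric(n); py <- numeric(n)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        r <- Rw * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
        cx <- r * cos(a); cy <- r * sin(a)
        if (i == 1L) break
        d2 <- (px[seq_len(i - 1L)] - cx)^2 + (py[seq_len(i - 1L)] - cy)^2
        if (min(d2) >= r_rep^2) break
      }
      px[i] <- cx; py[i] <- cy
    }
    th <- runif(n, 0, 2 * pi)
    X[1L, ] <- px; Y[1L, ] <- py

    for (t in seq_len(T_ - 1L)) {
      sp <- params$base_speed_mm_s * decay^((t - 1L) * dt / 60)
      ux <- cos(th); uy <- sin(th)
      if (n > 1L && att_w > 0) {
        ox <- (sum(px) - px) / (n - 1L) - px   # vector to centroid of others
        oy <- (sum(py) - py) / (n - 1L) - py
        nrm <- sqrt(ox^2 + oy^2)
        ok <- nrm > 1e-12
        ux <- ux + ifelse(ok, att_w * ox / pmax(nrm, 1e-12), 0)
        uy <- uy + ifelse(ok, att_w * oy / pmax(nrm, 1e-12), 0)
      }
      th <- atan2(uy, ux) + rnorm(n, 0, noise_sd)
      px <- px + sp * dt * cos(th)
      py <- py + sp * dt * sin(th)

      if (n > 1L && r_rep > 0) {
        dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
        d <- sqrt(dx^2 + dy^2)
        close <- which(upper.tri(d) & d < r_rep, arr.ind = TRUE)
        if (nrow(close)) {
          for (k in seq_len(nrow(close))) {
            i <- close[k, 1L]; j <- close[k, 2L]
            vx <- px[i] - px[j]; vy <- py[i] - py[j]
            dd <- sqrt(vx^2 + vy^2)
            if (dd < 1e-9) { a <- runif(1, 0, 2 * pi); vx <- cos(a); vy <- sin(a); dd <- 1 }
            push <- (r_rep - dd) / 2
            px[i] <- px[i] + push * vx / dd; py[i] <- py[i] + push * vy / dd
            px[j] <- px[j] - push * vx / dd; py[j] <- py[j] - push * vy / dd
          }
        }
      }

      rr <- sqrt(px^2 + py^2)
      out <- which(rr > Rw)
      if (length(out)) {
        nx <- px[out] / rr[out]; ny <- py[out] / rr[out]
        refl <- pmax(2 * Rw - rr[out], 0.001 * Rw)  # reflect radial overshoot
        px[out] <- refl * nx; py[out] <- refl * ny
        dot <- cos(th[out]) * nx + sin(th[out]) * ny
        th[out] <- atan2(sin(th[out]) - 2 * dot * ny, cos(th[out]) - 2 * dot * nx)
      }
      X[t + 1L, ] <- px; Y[t + 1L, ] <- py
    }
  })

  trajectory_set(X, Y, fps = params$fps, units = "mm",
                 arena = arena_spec(diameter_mm = params$arena_diameter_mm),
                 provenance = list(source = "simulate_group",
                                   params = unclass(params),
                                   seed = params$seed))
}
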