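# Cohort-level analytics: synthetic line cohorts, ranking, extreme-line
# selection, Spearman rank correlation, plasticity contrasts.

#' Simulate a cohort of synthetic fly lines
#'
#' Stand-in for a multi-line natural-variation screen: half the lines get the
#' clustering (`short_sd`) preset and half the dispersing (`long_sd`) preset,
#' each line receives a small lognormal jitter of its dynamics parameters
#' (so replicate lines differ as real genotypes do), and every line is
#' simulated `reps` times with independent derived seeds. Metrics are
#' computed with [group_metrics()].
#'
#' @param n_lines_per_regime lines per behavioral regime (>= 1).
#' @param reps replicate recordings per line (default 5, the per-line
#'   replication of the original screen).
#' @param base a [sim_params()] object giving the shared experiment constants.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param sd_mode,cv_estimator passed to [group_metrics()].
#' @return A `cohort_table`: data.frame with one row per recording
#'   (`line_id`, `regime` ground-truth label, `condition`, `replicate`,
#'   `seed`, and all [group_metrics()] columns).
#' @export
make_cohort <- function(n_lines_per_regime = 3, reps = 5, base = sim_params(),
                        seed = 1L, sd_mode = "mean_pairwise",
                        cv_estimator = "iqr_dispersion") {
  check_number(n_lines_per_regime, "n_lines_per_regime", min = 1, integer = TRUE)
  check_number(reps, "reps", min = 1, integer = TRUE)
  validate_sim_params(base)
  regimes <- rep(c("short_sd", "long_sd"), each = n_lines_per_regime)
  n_lines <- length(regimes)
  jit <- with_seed(seed, matrix(rnorm(n_lines * 3L, 0, 1), n_lines, 3L))
  sim_seeds <- derive_seeds(seed + 1L, n_lines * reps)
  rows <- vector("list", n_lines * reps)
  for (li in seq_len(n_lines)) {
    p <- apply_overrides(base, behavior_regime(regimes[li]))
    # line-specific lognormal jitter: genotype-like variation around presets
    p <- apply_overrides(p, list(
      attraction = p$attraction * exp(0.15 * jit[li, 1L]),
      speed_decay_per_min = min(1, p$speed_decay_per_min * exp(0.10 * jit[li, 2L])),
      base_speed_mm_s = p$base_speed_mm_s * exp(0.08 * jit[li, 3L])
    ))
    for (r in seq_len(reps)) {
      k <- (li - 1L) * reps + r
      pr <- apply_overrides(p, list(seed = sim_seeds[k]))
      gm <- group_metrics(simulate_group(pr), sd_mode = sd_mode,
                          cv_estimator = cv_estimator)
      rows[[k]] <- cbind(
        data.frame(line_id = sprintf("line_%02d", li), regime = regimes[li],
                   condition = "grouped.control", replicate = r,
                   seed = sim_seeds[k]),
        as.data.frame(gm))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Rank lines by their mean phenotypes
#'
#' Replicates are averaged per line first, then each metric is ranked
#' ascending (rank 1 = smallest, i.e. shortest SD / slowest) with midranks
#' for ties; the average rank over `metric_set` orders lines from most to
#' least clustering.
#'
#' @param records a `cohort_table` (or any data.frame with `line_id`,
#'   `condition`, and the metric columns).
#' @param metric_set character vector of metric column names (default the
#'   two screen metrics: overall SD and centroid velocity).
#' @param condition which condition's replicates to use (default
#'   `"grouped.control"`); `NULL` uses all records.
#' @return A `rank_table` data.frame: per line, the mean metric values,
#'   per-metric ranks `rank_<metric>`, and `avg_rank`; sorted by `line_id`.
#' @export
rank_lines <- function(records, metric_set = c("sd_overall", "centroid_velocity"),
                       condition = "grouped.control") {
  if (!length(metric_set)) snb_stop("snb_stat_error", "empty metric set")
  missing_cols <- setdiff(c("line_id", metric_set), names(records))
  if (length(missing_cols))
    stop_param(missing_cols[1L], "column not present in cohort records")
  if (!is.null(condition)) {
    records <- records[records$condition %in% condition, , drop = FALSE]
    if (!nrow(records))
      snb_stop("snb_stat_error", "no records in condition '%s'", condition)
  }
  agg <- aggregate(records[metric_set], by = list(line_id = records$line_id), mean)
  agg <- agg[order(agg$line_id), , drop = FALSE]
  for (m in metric_set)
    agg[[paste0("rank_", m)]] <- rank(agg[[m]], ties.method = "average")
  agg$avg_rank <- rowMeans(agg[paste0("rank_", metric_set)])
  rownames(agg) <- NULL
  class(agg) <- c("rank_table", "data.frame")
  agg
}

#' Select extreme lines by average rank
#'
#' The bottom-k lines (lowest average rank: strongest clustering, shortest
#' SD) and top-k lines (highest average rank). Ties in average rank are
#' broken by `line_id` lexicographic order, so the selection is
#' deterministic.
#'
#' @param rank_table output of [rank_lines()].
#' @param k lines per extreme; `2k` must not exceed the number of lines.
#' @return List with `bottom` and `top` character vectors of line ids.
#' @export
select_extremes <- function(rank_table, k) {
  check_number(k, "k", min = 0, integer = TRUE)
  n <- nrow(rank_table)
  if (2 * k > n)
    snb_stop("snb_stat_error", "cannot select 2*%d extremes from %d lines", k, n)
  ord <- order(rank_table$avg_rank, rank_table$line_id)
  ids <- rank_table$line_id[ord]
  list(bottom = if (k > 0) ids[seq_len(k)] else character(0),
       top = if (k > 0) rev(ids)[seq_len(k)][k:1] else character(0))
}

midranks <- function(v) {
  o <- order(v)
  n <- length(v)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

rho_from_ranks <- function(rx, ry) {
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0)
    snb_stop("snb_stat_error", "Spearman correlation undefined for constant input")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Tie-safe Spearman rank correlation
#'
#' rho is the Pearson correlation of the midrank-transformed inputs (exact
#' under ties). When `n_perm > 0`, a two-sided permutation p-value is
#' computed by randomly permuting `y` (`p = (1 + #{|rho*| >= |rho|}) /
#' (n_perm + 1)`), seeded for reproducibility.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no NAs.
#' @param n_perm number of random permutations for the p-value (0 = skip;
#'   default 10000 when requested downstream).
#' @param seed RNG seed for the permutations.
#' @return List with `rho`, `p_value` (`NA` if `n_perm = 0`), `n`, `n_perm`.
#' @examples
#' spearman_rho(1:6, c(2, 1, 4, 3, 6, 5))$rho
#' @export
spearman_rho <- function(x, y, n_perm = 0L, seed = 1L) {
  if (length(x) != length(y)) stop_param("x/y", "lengths differ")
  n <- length(x)
  if (n < 3L) stop_param("x/y", "need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_param("x/y", "NA values not allowed")
  check_number(n_perm, "n_perm", min = 0, integer = TRUE)
  rx <- midranks(x); ry <- midranks(y)
  rho <- rho_from_ranks(rx, ry)
  p <- NA_real_
  if (n_perm > 0L) {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(rho_from_ranks(rx, ry[sample.int(n)])) >= abs(rho) - 1e-12
      }, logical(1)))
    })
    p <- (1 + hits) / (n_perm + 1)
  }
  list(rho = rho, p_value = p, n = n, n_perm = as.integer(n_perm))
}

#' Per-line plasticity contrast
#'
#' For each line, the change in a metric between a baseline and a challenge
#' condition (`delta = mean(challenge) - mean(baseline)` over replicates).
#' For injury contrasts on the SD metric, negative delta means
#' injury-induced clustering. Lines missing either condition are flagged in
#' `status`, never silently dropped.
#'
#' @param records a `cohort_table` with a `condition` column.
#' @param baseline,challenge condition labels (e.g. `"grouped.control"`,
#'   `"grouped.injured"`).
#' @param metric metric column to contrast (default `"sd_overall"`).
#' @return data.frame sorted by `line_id`: per line, the two condition
#'   means, replicate counts and SDs, `delta`, and `status` (`"ok"` or
#'   `"missing_condition"`).
#' @export
plasticity_contrast <- function(records, baseline, challenge,
                                metric = "sd_overall") {
  for (col in c("line_id", "condition", metric))
    if (!col %in% names(records)) stop_param(col, "column not present in records")
  lines <- sort(unique(records$line_id))
  res <- lapply(lines, function(id) {
    b <- records[records$line_id == id & records$condition == baseline, metric]
    c_ <- records[records$line_id == id & records$condition == challenge, metric]
    data.frame(
      line_id = id,
      baseline_mean = if (length(b)) mean(b) else NA_real_,
      challenge_mean = if (length(c_)) mean(c_) else NA_real_,
      delta = if (length(b) && length(c_)) mean(c_) - mean(b) else NA_real_,
      n_baseline = length(b), n_challenge = length(c_),
      baseline_sd = if (length(b) > 1L) sd(b) else NA_real_,
      challenge_sd = if (length(c_) > 1L) sd(c_) else NA_real_,
      status = if (length(b) && length(c_)) "ok" else "missing_condition")
  })
  do.call(rbind, res)
}

#' Simulate a plasticity cohort (rearing x injury design)
#'
#' Generates recordings for lines under the four conditions
#' `{grouped, isolated} x {control, injured}`. All lines start from the
#' dispersing (`long_sd`) preset; injury applies [injury_overrides()] only
#' to group-reared ("socialized") flies, so grouped lines cluster after
#' injury while developmentally isolated lines are insensitive — the
#' modeled plasticity pattern.
#'
#' @param n_lines_per_rearing lines per rearing condition.
#' @param reps replicate recordings per line and condition (default 8).
#' @param base a [sim_params()] object.
#' @param seed integer seed.
#' @return A `cohort_table` with conditions `<rearing>.<treatment>`.
#' @export
simulate_plasticity_cohort <- function(n_lines_per_rearing = 2, reps = 8,
                                       base = sim_params(), seed = 1L) {
  check_number(n_lines_per_rearing, "n_lines_per_rearing", min = 1, integer = TRUE)
  check_number(reps, "reps", min = 1, integer = TRUE)
  rearing <- rep(c("grouped", "isolated"), each = n_lines_per_rearing)
  n_lines <- length(rearing)
  conditions <- c("control", "injured")
  sim_seeds <- derive_seeds(seed, n_lines * length(conditions) * reps)
  rows <- list(); k <- 0L
  for (li in seq_len(n_lines)) {
    p_line <- apply_overrides(base, behavior_regime("long_sd"))
    for (cond in conditions) {
      p <- p_line
      if (cond == "injured") p <- apply_injury(p, socialized = rearing[li] == "grouped")
      for (r in seq_len(reps)) {
        k <- k + 1L
        pr <- apply_overrides(p, list(seed = sim_seeds[k]))
        gm <- group_metrics(simulate_group(pr))
        rows[[k]] <- cbind(
          data.frame(line_id = sprintf("%s_%02d", substr(rearing[li], 1, 3), li),
                     regime = rearing[li],
                     condition = paste(rearing[li], cond, sep = "."),
                     replicate = r, seed = sim_seeds[k]),
          as.data.frame(gm))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
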