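# internal helpers: parameter validation, seeded evaluation, flag codes

FLAG_OBSERVED <- 0L
FLAG_INTERPOLATED <- 1L
FLAG_MISSING <- 2L
FLAG_LEVELS <- c("observed", "interpolated", "missing")

snb_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "snb_error")))
}

stop_param <- function(field, fmt, ...) {
  snb_stop("snb_param_error", paste0("invalid parameter '", field, "': ", fmt), ...)
}

check_number <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(field, "must be a single finite number")
  if (integer && x != round(x)) stop_param(field, "must be an integer")
  if (strict_min && x <= min) stop_param(field, "must be > %g", min)
  if (!strict_min && x < min) stop_param(field, "must be >= %g", min)
  if (x > max) stop_param(field, "must be <= %g", max)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive k child seeds from a parent seed, each a valid 32-bit integer.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

flag_to_chr <- function(flag) FLAG_LEVELS[flag + 1L]

chr_to_flag <- function(chr) {
  idx <- match(chr, FLAG_LEVELS)
  if (anyNA(idx)) snb_stop("snb_parse_error", "unknown flag value '%s'",
                           chr[which(is.na(idx))[1L]])
  idx - 1L
}
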