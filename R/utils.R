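# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when one is supplied, otherwise use the
# current RNG stream. All user-facing stochastic functions route through this
# so that a single `seed` argument makes them fully reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Scalar checks -------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(as.integer(x))
}

check_binary <- function(y, name = "Y") {
  if (!is.numeric(y) && !is.logical(y)) {
    abort(sprintf("`%s` must be numeric or logical.", name))
  }
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0 and 1.", name))
  }
  y
}

# Interval tibbles ----------------------------------------------------------

check_intervals <- function(x, name = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf(
      "`%s` must be a data frame with columns `chrom`, `start`, `end`.", name
    ))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort(sprintf(
      "`%s` has invalid coordinates: require 0 <= start < end.", name
    ))
  }
  invisible(x)
}

# TADs on one chromosome must be sorted and non-overlapping before border
# points can be defined; returns the intervals sorted by (chrom, start).
sort_check_disjoint <- function(x, name = "tads") {
  check_intervals(x, name)
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  bad <- x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      overlap = any(.data$start[-1] < .data$end[-dplyr::n()]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$overlap)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "`%s` contains overlapping intervals on chromosome(s): %s.",
      name, paste(bad$chrom, collapse = ", ")
    ))
  }
  x
}
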