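#' Align two release profiles onto a common time grid
#'
#' Takes the intersection of the two sampling schedules (times matching
#' within 1e-6 day) and returns the paired mean percent-released series.
#' By default no interpolation is performed; with `interpolate = TRUE` the
#' test profile is linearly interpolated onto the reference grid (restricted
#' to the overlap of the two spans).
#'
#' @param reference,test `cumulative_profile` objects.
#' @param interpolate Interpolate `test` onto the reference grid instead of
#'   intersecting grids.
#' @return A list with `times`, `reference`, `test` (percent released).
#' @export
align_timepoints <- function(reference, test, interpolate = FALSE) {
  stopifnot(inherits(reference, "cumulative_profile"),
            inherits(test, "cumulative_profile"))
  rt <- reference$times_days; rv <- reference$fraction_released * 100
  tt <- test$times_days;      tv <- test$fraction_released * 100
  if (interpolate) {
    keep <- rt >= min(tt) - 1e-6 & rt <= max(tt) + 1e-6
    if (!any(keep)) stop("profiles do not span a common interval", call. = FALSE)
    ti <- stats::approx(tt, tv, xout = pmin(pmax(rt[keep], min(tt)), max(tt)))$y
    return(list(times = rt[keep], reference = rv[keep], test = ti))
  }
  idx <- outer(rt, tt, function(a, b) abs(a - b) < 1e-6)
  ri <- which(rowSums(idx) > 0)
  if (!length(ri)) {
    stop("no common sampling times; rerun with interpolate = TRUE", call. = FALSE)
  }
  ti <- apply(idx[ri, , drop = FALSE], 1, which.max)
  list(times = rt[ri], reference = rv[ri], test = tv[ti])
}

#' f2 similarity factor between two dissolution profiles
#'
#' `f2 = 50 * log10(100 / sqrt(1 + sum((R_t - T_t)^2) / n))`, a logarithmic
#' transform of the mean squared difference between the mean percent released
#' of a reference and a test formulation at matched times. Values in
#' 50-100 indicate similar profiles (an average pointwise difference of at
#' most ~10 percentage points); identical profiles give exactly 100.
#'
#' Following the standard regulatory convention, once either profile reaches
#' 85% dissolved the comparison window is truncated: all times strictly
#' before the first such time are retained, plus that first time itself, and
#' later points are dropped.
#'
#' @param reference,test Mean percent-released series on a common grid
#'   (from [align_timepoints()]), or two `cumulative_profile` objects
#'   (fractions are converted to percent internally — f2 is only meaningful
#'   on the percent scale).
#' @param times Sampling times (required when the series are numeric).
#' @return A `similarity_result`: `f2`, `n_used`, `truncated_at` (first
#'   excluded time, or `NA` if none was dropped), `verdict`
#'   (`"similar"` iff `50 <= f2 <= 100`).
#' @export
compute_f2 <- function(reference, test, times = NULL) {
  if (inherits(reference, "cumulative_profile")) {
    al <- align_timepoints(reference, test)
    reference <- al$reference; test <- al$test; times <- al$times
  }
  if (is.null(times)) stop("`times` required for numeric series", call. = FALSE)
  if (length(reference) != length(test) || length(reference) != length(times)) {
    stop("series and times differ in length; use align_timepoints()", call. = FALSE)
  }
  if (!length(reference)) stop("no timepoints to compare", call. = FALSE)

  hit <- which(reference >= 85 | test >= 85)
  if (length(hit)) {
    keep <- seq_len(hit[1])                # retain the first point at >= 85%
    truncated_at <- if (hit[1] < length(times)) times[hit[1] + 1L] else NA_real_
  } else {
    keep <- seq_along(times)
    truncated_at <- NA_real_
  }
  r <- reference[keep]; s <- test[keep]
  n <- length(keep)
  if (anyNA(r) || anyNA(s)) stop("NA percent values in the retained window", call. = FALSE)
  f2 <- 50 * log10(100 / sqrt(1 + sum((r - s)^2) / n))
  structure(
    list(f2 = f2, n_used = n, truncated_at = truncated_at,
         verdict = if (f2 >= 50 && f2 <= 100) "similar" else "not-similar"),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> f2 = %.2f over %d point(s)%s -> %s\n",
              x$f2, x$n_used,
              if (is.na(x$truncated_at)) ""
              else sprintf(" (truncated from %g d)", x$truncated_at),
              x$verdict))
  invisible(x)
}
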