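#' Cumulative release profile from sample-and-replace measurements
#'
#' Reconstructs the cumulative amount of analyte released per mg of
#' microspheres from supernatant concentrations under full-medium
#' replacement: because the entire medium is removed and replaced at every
#' sampling, the amount released in interval k is simply `C_k * V`, and the
#' cumulative amount at sampling k is the running sum
#' `sum_{i<=k}(C_i * V) / mass`.
#'
#' Replicates are accumulated independently; the mean and SD are taken
#' across replicates at each time, and the released fraction is the replicate
#' mean divided by the analyte loading (mean-then-fraction, as release
#' figures report mean +/- SD in amount units). A missing cell makes that
#' replicate's cumulative series unknown (`NA`) from that time onward —
#' later sums cannot be formed without the lost increment — and the
#' remaining replicates carry the mean.
#'
#' @param assay A [release_assay()].
#' @param analyte Analyte name present in the assay.
#' @return An object of class `cumulative_profile`: `analyte`, `unit`,
#'   `times_days`, `per_replicate` (replicates x times matrix, amount/mg),
#'   `mean_cumulative`, `sd_cumulative` (amount/mg), `fraction_released`
#'   (dimensionless; values > 1 are allowed but flagged via
#'   `over_release`), and `loading_per_mg`.
#' @export
cumulative_from_samples <- function(assay, analyte) {
  stopifnot(inherits(assay, "release_assay"))
  if (assay$sample_mass_mg <= 0 || assay$medium_volume_ml <= 0) {
    stop("sample mass and medium volume must be positive", call. = FALSE)
  }
  if (!analyte %in% names(assay$loadings)) {
    stop("analyte not present in assay: ", analyte, call. = FALSE)
  }
  m <- assay$measurements[assay$measurements$analyte == analyte, , drop = FALSE]
  if (!nrow(m)) stop("no measurements for analyte: ", analyte, call. = FALSE)
  times <- assay$times_days
  reps <- sort(unique(m$replicate))

  per_rep <- matrix(NA_real_, nrow = length(reps), ncol = length(times),
                    dimnames = list(replicate = reps, time = times))
  for (i in seq_along(reps)) {
    mi <- m[m$replicate == reps[i], , drop = FALSE]
    mi <- mi[match(times, mi$time_days), , drop = FALSE]
    amt <- mi$concentration * assay$medium_volume_ml   # amount per interval
    per_rep[i, ] <- cumsum(amt) / assay$sample_mass_mg # NA propagates forward
  }

  mean_cum <- apply(per_rep, 2, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  sd_cum <- apply(per_rep, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::sd(x)
  })
  loading <- assay$loadings[[analyte]]$loading_per_mg
  frac <- mean_cum / loading

  structure(
    list(analyte = analyte, unit = assay$loadings[[analyte]]$unit,
         times_days = times, per_replicate = per_rep,
         mean_cumulative = unname(mean_cum), sd_cumulative = unname(sd_cum),
         fraction_released = unname(frac), loading_per_mg = loading,
         over_release = any(frac > 1, na.rm = TRUE)),
    class = "cumulative_profile"
  )
}

#' Construct a cumulative profile directly from a fraction series
#'
#' Convenience constructor used when a mean release curve is already in hand
#' (e.g. digitised or simulated fractions) and only the fitting/similarity
#' stages are needed.
#'
#' @param times_days Strictly increasing sampling times, days.
#' @param fraction Released fraction at each time (same length).
#' @param analyte Label, defaults to `"analyte"`.
#' @param loading_per_mg Loading used to express amounts; defaults to 1 so
#'   that amount/mg equals the fraction.
#' @return A `cumulative_profile`.
#' @export
profile_from_fraction <- function(times_days, fraction, analyte = "analyte",
                                  loading_per_mg = 1) {
  stopifnot(length(times_days) == length(fraction),
            all(diff(times_days) > 0), all(times_days > 0))
  structure(
    list(analyte = analyte, unit = "ug/mg", times_days = as.numeric(times_days),
         per_replicate = matrix(fraction * loading_per_mg, nrow = 1,
                                dimnames = list(replicate = 1, time = times_days)),
         mean_cumulative = as.numeric(fraction * loading_per_mg),
         sd_cumulative = rep(0, length(fraction)),
         fraction_released = as.numeric(fraction),
         loading_per_mg = loading_per_mg,
         over_release = any(fraction > 1, na.rm = TRUE)),
    class = "cumulative_profile"
  )
}

#' @export
print.cumulative_profile <- function(x, ...) {
  cat(sprintf("<cumulative_profile> %s: %d times (%g..%g d), %d replicate(s)\n",
              x$analyte, length(x$times_days), min(x$times_days),
              max(x$times_days), nrow(x$per_replicate)))
  cat(sprintf("  final mean release: %.4g %s (fraction %.4f)%s\n",
              x$mean_cumulative[length(x$mean_cumulative)], x$unit,
              x$fraction_released[length(x$fraction_released)],
              if (isTRUE(x$over_release)) " [exceeds loading]" else ""))
  invisible(x)
}

#' Model-free burst release at 24 h
#'
#' The burst is the amount released during the first day of the assay,
#' before the profile settles into its sustained phase — the "experimental
#' B" of the release-parameter table. It is read off the profile at the
#' sampling time nearest one day (tolerance +/- 0.5 d); no extrapolation is
#' attempted, so a schedule with no sampling near 24 h has no defined burst.
#'
#' @param profile A [cumulative_from_samples()] profile.
#' @return An object of class `burst_summary`: `analyte`, `time_days`,
#'   `burst_amount_per_mg`, `burst_fraction`.
#' @export
experimental_burst <- function(profile) {
  stopifnot(inherits(profile, "cumulative_profile"))
  t <- profile$times_days
  i <- which(t >= 0.5 & t <= 1.5)
  if (!length(i)) {
    stop("burst undefined: no sampling time within [0.5, 1.5] days", call. = FALSE)
  }
  i <- i[which.min(abs(t[i] - 1))]
  structure(
    list(analyte = profile$analyte, time_days = t[i],
         burst_amount_per_mg = profile$mean_cumulative[i],
         burst_fraction = profile$fraction_released[i]),
    class = "burst_summary"
  )
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf("<burst_summary> %s: %.4g per mg (fraction %.4f) at %g d\n",
              x$analyte, x$burst_amount_per_mg, x$burst_fraction, x$time_days))
  invisible(x)
}

#' Mean release rate over a time interval
#'
#' Average slope of the mean cumulative curve between two times inside the
#' observed span, in amount/mg/day; endpoints falling between sampling times
#' are linearly interpolated.
#'
#' @param profile A `cumulative_profile`.
#' @param t_start,t_end Interval bounds in days, `t_start < t_end`, both
#'   within `[min(times), max(times)]`.
#' @return Release rate, amount per mg per day.
#' @export
interval_release_rate <- function(profile, t_start, t_end) {
  stopifnot(inherits(profile, "cumulative_profile"))
  if (!(t_start < t_end)) stop("`t_start` must be < `t_end`", call. = FALSE)
  t <- profile$times_days
  if (t_start < min(t) || t_end > max(t)) {
    stop(sprintf("interval [%g, %g] outside observed span [%g, %g]",
                 t_start, t_end, min(t), max(t)), call. = FALSE)
  }
  y <- profile$mean_cumulative
  v <- stats::approx(t, y, xout = c(t_start, t_end))$y
  (v[2] - v[1]) / (t_end - t_start)
}
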