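#' Analyte loading metadata
#'
#' Describes how much of one active compound a batch of microspheres carries.
#' The loading is expressed per mg of particles in the analyte's own mass
#' unit (micrograms per mg for small molecules, nanograms per mg for
#' proteins); no cross-analyte unit coercion is ever performed, because
#' protein payloads are typically three orders of magnitude below the small
#' molecules.
#'
#' @param analyte Character scalar naming the analyte (e.g. `"DX"`).
#' @param loading_per_mg Positive amount of analyte per mg of microspheres.
#' @param unit Mass unit of the loading, `"ug/mg"` or `"ng/mg"`.
#' @param entrapment_fraction Encapsulation efficiency as a fraction of the
#'   theoretical payload. Values slightly above 1 are tolerated (up to 1.2):
#'   extraction/quantification uncertainty routinely yields nominal
#'   efficiencies just over 100%.
#' @return An object of class `analyte_loading`.
#' @export
analyte_loading <- function(analyte, loading_per_mg, unit = c("ug/mg", "ng/mg"),
                            entrapment_fraction = NA_real_) {
  unit <- match.arg(unit)
  stopifnot(is.character(analyte), length(analyte) == 1L, nzchar(analyte))
  if (!is.numeric(loading_per_mg) || length(loading_per_mg) != 1L ||
      !is.finite(loading_per_mg) || loading_per_mg <= 0) {
    stop("`loading_per_mg` must be a single positive number", call. = FALSE)
  }
  if (!is.na(entrapment_fraction) &&
      (entrapment_fraction <= 0 || entrapment_fraction > 1.2)) {
    stop("`entrapment_fraction` must lie in (0, 1.2]", call. = FALSE)
  }
  structure(
    list(analyte = analyte, loading_per_mg = as.numeric(loading_per_mg),
         unit = unit, entrapment_fraction = as.numeric(entrapment_fraction)),
    class = "analyte_loading"
  )
}

#' In vitro release assay
#'
#' Container for a sample-and-replace dissolution experiment: a known mass of
#' microspheres suspended in a fixed medium volume, with the whole medium
#' removed and replaced at each sampling time and the supernatant
#' concentration of each analyte measured per replicate.
#'
#' Missing cells (lost samples) are allowed and carried explicitly as `NA`
#' concentrations; they are never silently dropped, and downstream replicate
#' means use the replicates that remain.
#'
#' @param sample_mass_mg Microsphere mass per replicate vial, mg (> 0).
#' @param medium_volume_ml Medium volume removed and replaced at each
#'   sampling, mL (> 0).
#' @param loadings List of [analyte_loading()] objects, one per analyte.
#' @param measurements Data frame with columns `time_days`, `replicate`,
#'   `analyte`, `concentration` (amount per mL in the analyte's unit;
#'   `NA` marks a lost sample). One row per cell; duplicates are an error.
#' @return An object of class `release_assay` with fields `sample_mass_mg`,
#'   `medium_volume_ml`, `loadings` (named by analyte), `times_days`
#'   (sorted unique times), `n_replicates`, and the validated `measurements`
#'   table (every time/replicate/analyte cell present, missing ones as `NA`).
#' @export
release_assay <- function(sample_mass_mg, medium_volume_ml, loadings,
                          measurements) {
  if (!is.numeric(sample_mass_mg) || sample_mass_mg <= 0) {
    stop("`sample_mass_mg` must be > 0", call. = FALSE)
  }
  if (!is.numeric(medium_volume_ml) || medium_volume_ml <= 0) {
    stop("`medium_volume_ml` must be > 0", call. = FALSE)
  }
  if (inherits(loadings, "analyte_loading")) loadings <- list(loadings)
  if (!length(loadings) || !all(vapply(loadings, inherits, TRUE, "analyte_loading"))) {
    stop("`loadings` must be a list of analyte_loading objects", call. = FALSE)
  }
  names(loadings) <- vapply(loadings, `[[`, character(1), "analyte")
  if (anyDuplicated(names(loadings))) {
    stop("duplicate analyte in `loadings`", call. = FALSE)
  }

  req <- c("time_days", "replicate", "analyte", "concentration")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements))) {
    stop("`measurements` needs columns time_days, replicate, analyte, concentration",
         call. = FALSE)
  }
  m <- measurements[req]
  m$time_days <- as.numeric(m$time_days)
  m$replicate <- as.integer(m$replicate)
  m$analyte <- as.character(m$analyte)
  m$concentration <- as.numeric(m$concentration)

  unknown <- setdiff(unique(m$analyte), names(loadings))
  if (length(unknown)) {
    stop("measurements reference unknown analyte(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(m$time_days, m$replicate, m$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (time, replicate, analyte) measurement rows: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "),
         call. = FALSE)
  }
  bad <- which(!is.na(m$concentration) & m$concentration < 0)
  if (length(bad)) {
    stop(sprintf(
      "negative concentration at time %g, replicate %d, analyte %s",
      m$time_days[bad[1]], m$replicate[bad[1]], m$analyte[bad[1]]), call. = FALSE)
  }

  times <- sort(unique(m$time_days))
  if (length(times) && (any(times <= 0) || any(diff(times) <= 0))) {
    stop("sampling times must be strictly increasing and > 0", call. = FALSE)
  }
  reps <- sort(unique(m$replicate))
  n_rep <- max(1L, length(reps))

  # complete the grid: absent cells become explicit NA (flagged missing)
  if (nrow(m)) {
    grid <- expand.grid(time_days = times, replicate = reps,
                        analyte = names(loadings)[names(loadings) %in% unique(m$analyte)],
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- merge(grid, m, by = c("time_days", "replicate", "analyte"),
               all.x = TRUE, sort = FALSE)
    m <- m[order(m$analyte, m$replicate, m$time_days), , drop = FALSE]
    rownames(m) <- NULL
  }
  m$missing <- is.na(m$concentration)

  structure(
    list(sample_mass_mg = as.numeric(sample_mass_mg),
         medium_volume_ml = as.numeric(medium_volume_ml),
         loadings = loadings, times_days = times,
         n_replicates = n_rep, measurements = m),
    class = "release_assay"
  )
}

#' @export
print.release_assay <- function(x, ...) {
  cat(sprintf("<release_assay> %g mg microspheres in %g mL medium\n",
              x$sample_mass_mg, x$medium_volume_ml))
  cat(sprintf("  analytes: %s\n", paste(names(x$loadings), collapse = ", ")))
  cat(sprintf("  %d sampling times (%g..%g d), %d replicate(s), %d cells (%d missing)\n",
              length(x$times_days),
              if (length(x$times_days)) min(x$times_days) else NA,
              if (length(x$times_days)) max(x$times_days) else NA,
              x$n_replicates, nrow(x$measurements), sum(x$measurements$missing)))
  invisible(x)
}

#' Read assay metadata from a JSON key-value file
#'
#' The metadata file carries the assay geometry and per-analyte loadings:
#' `{"sample_mass_mg": 5, "medium_volume_ml": 2, "loadings":
#'  {"DX": {"loading_per_mg": 95.79, "unit": "ug/mg",
#'          "entrapment_fraction": 0.8612}}}`.
#'
#' @param path Path to a JSON file.
#' @return A list with `sample_mass_mg`, `medium_volume_ml` and a list of
#'   [analyte_loading()] objects.
#' @export
read_assay_meta <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(meta$sample_mass_mg) || is.null(meta$medium_volume_ml) ||
      is.null(meta$loadings)) {
    stop("metadata must supply sample_mass_mg, medium_volume_ml and loadings",
         call. = FALSE)
  }
  loadings <- lapply(names(meta$loadings), function(a) {
    l <- meta$loadings[[a]]
    analyte_loading(a, l$loading_per_mg,
                    unit = if (is.null(l$unit)) "ug/mg" else l$unit,
                    entrapment_fraction =
                      if (is.null(l$entrapment_fraction)) NA_real_
                      else l$entrapment_fraction)
  })
  list(sample_mass_mg = as.numeric(meta$sample_mass_mg),
       medium_volume_ml = as.numeric(meta$medium_volume_ml),
       loadings = loadings)
}

#' Write assay metadata to JSON
#'
#' @param assay A `release_assay`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_meta <- function(assay, path) {
  stopifnot(inherits(assay, "release_assay"))
  loadings <- lapply(assay$loadings, function(l) {
    out <- list(loading_per_mg = l$loading_per_mg, unit = l$unit)
    if (!is.na(l$entrapment_fraction)) out$entrapment_fraction <- l$entrapment_fraction
    out
  })
  jsonlite::write_json(
    list(sample_mass_mg = assay$sample_mass_mg,
         medium_volume_ml = assay$medium_volume_ml,
         loadings = loadings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a release assay from delimited text
#'
#' Reads a comma-delimited measurement table with the fixed header
#' `time_days,replicate,analyte,concentration` and combines it with assay
#' metadata into a validated [release_assay()]. Missing cells (absent rows or
#' empty concentrations) are flagged, not dropped; negative concentrations,
#' duplicate cells and analytes absent from the metadata are errors.
#'
#' @param path Path to the CSV measurement file.
#' @param meta Either a path to a JSON metadata file (see
#'   [read_assay_meta()]) or a list with `sample_mass_mg`,
#'   `medium_volume_ml`, `loadings`.
#' @return A `release_assay`.
#' @export
read_assay <- function(path, meta) {
  if (is.character(meta)) meta <- read_assay_meta(meta)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_days", "replicate", "analyte", "concentration")
  if (!all(req %in% names(d))) {
    stop("assay file must have header time_days,replicate,analyte,concentration",
         call. = FALSE)
  }
  release_assay(meta$sample_mass_mg, meta$medium_volume_ml, meta$loadings, d)
}

#' Write a release assay to delimited text
#'
#' Emits the measurement table with the fixed header
#' `time_days,replicate,analyte,concentration`, concentrations printed as
#' full-precision decimal text (`%.17g`, so a write/read round trip restores
#' every value bit-for-bit). Missing cells are written with an empty
#' concentration field.
#'
#' @param assay A `release_assay`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path) {
  stopifnot(inherits(assay, "release_assay"))
  m <- assay$measurements
  lines <- "time_days,replicate,analyte,concentration"
  if (nrow(m)) {
    conc <- ifelse(is.na(m$concentration), "",
                   sprintf("%.17g", m$concentration))
    lines <- c(lines, sprintf("%.17g,%d,%s,%s",
                              m$time_days, m$replicate, m$analyte, conc))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write assay file: ", path, call. = FALSE)
  invisible(path)
}
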