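# djb2-style accumulator over the serialized object: cheap, dependency-free
# content hash used to make pipeline runs auditable. Stays below 2^53 so the
# double arithmetic is exact.
.relkin_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Full release characterization of one or more assays
#'
#' Chains the pipeline stages the way a release study is reported: for every
#' assay and analyte, build the cumulative profile, quantify the 24-h burst,
#' fit and rank the kinetic model catalog, tabulate the burst-corrected
#' biphasic (Gallagher-Corrigan/Gorrasi) parameters, and compute the f2
#' similarity factor for the declared profile pairs. Stage failures are
#' recorded per analyte and the bundle is still emitted — nothing is
#' silently dropped.
#'
#' @param assays Named list of [release_assay()] objects (names identify the
#'   formulation).
#' @param models Model catalog to rank (default: the full catalog).
#' @param f2_pairs List of pairs for similarity testing; each element is a
#'   list with `reference` and `test`, both `"assay:analyte"` keys.
#' @param config A [fit_config()] controlling seeds and multistart.
#' @param verbose Log each stage (with input content hashes) via
#'   [message()].
#' @return A `report_bundle`: `profiles`, `burst` (table), `comparisons`,
#'   `gcg_table` (Experimental B | B | Y1 | k1 | Y2 | k2 | t2 layout, plus
#'   fit diagnostics and a `converged` flag per row), `f2`, `failures`, and
#'   `metadata` (seed, config hash, package version).
#' @export
characterize <- function(assays, models = list_models(), f2_pairs = list(),
                         config = fit_config(), verbose = FALSE) {
  if (!length(assays)) stop("supply at least one assay", call. = FALSE)
  if (is.null(names(assays)) || any(!nzchar(names(assays)))) {
    stop("`assays` must be a named list", call. = FALSE)
  }
  stopifnot(all(vapply(assays, inherits, TRUE, "release_assay")))
  say <- function(...) if (verbose) message(sprintf(...))
  failures <- list()
  fail <- function(stage, key, e) {
    failures[[length(failures) + 1L]] <<- data.frame(
      stage = stage, key = key, message = conditionMessage(e),
      stringsAsFactors = FALSE)
    NULL
  }

  profiles <- list(); bursts <- list(); comparisons <- list(); gcg_rows <- list()
  for (an in names(assays)) {
    assay <- assays[[an]]
    say("assay %s [%s]: %d analytes", an, .relkin_hash(assay$measurements),
        length(assay$loadings))
    for (a in names(assay$loadings)) {
      key <- paste0(an, ":", a)
      prof <- tryCatch(cumulative_from_samples(assay, a),
                       error = function(e) fail("cumulate", key, e))
      profiles[[key]] <- prof

      b <- if (!is.null(prof)) {
        tryCatch(experimental_burst(prof), error = function(e) fail("burst", key, e))
      }
      bursts[[key]] <- data.frame(
        assay = an, analyte = a,
        time_days = if (is.null(b)) NA_real_ else b$time_days,
        burst_amount_per_mg = if (is.null(b)) NA_real_ else b$burst_amount_per_mg,
        burst_fraction = if (is.null(b)) NA_real_ else b$burst_fraction,
        stringsAsFactors = FALSE)

      cmp <- if (!is.null(prof)) {
        tryCatch(compare_models(prof, models, config),
                 error = function(e) fail("compare_models", key, e))
      }
      comparisons[[key]] <- cmp
      say("  %s: burst %.4f, selected %s", key,
          bursts[[key]]$burst_fraction,
          if (is.null(cmp)) "<failed>" else cmp$selected)

      gcg <- if (!is.null(prof)) {
        tryCatch(fit_model(prof, "gallagher_corrigan_gorrasi", config),
                 error = function(e) fail("gcg_fit", key, e))
      }
      pr <- if (is.null(gcg)) stats::setNames(rep(NA_real_, 6),
                                              c("b", "Y1", "k1", "Y2", "k2", "t2"))
            else gcg$params
      gcg_rows[[key]] <- data.frame(
        assay = an, analyte = a,
        experimental_b = bursts[[key]]$burst_fraction,
        b = pr[["b"]], Y1 = pr[["Y1"]], k1 = pr[["k1"]],
        Y2 = pr[["Y2"]], k2 = pr[["k2"]], t2 = pr[["t2"]],
        sse = if (is.null(gcg)) NA_real_ else gcg$sse,
        r2_adjusted = if (is.null(gcg)) NA_real_ else gcg$r2_adjusted,
        converged = if (is.null(gcg)) FALSE else gcg$converged,
        stringsAsFactors = FALSE)
    }
  }

  f2_results <- list()
  for (pair in f2_pairs) {
    key <- paste0(pair$reference, " vs ", pair$test)
    f2_results[[key]] <- tryCatch({
      pr <- profiles[[pair$reference]]; pt <- profiles[[pair$test]]
      if (is.null(pr) || is.null(pt)) stop("unknown profile key", call. = FALSE)
      compute_f2(pr, pt)
    }, error = function(e) fail("f2", key, e))
    if (!is.null(f2_results[[key]])) say("  f2 %s = %.2f", key, f2_results[[key]]$f2)
  }

  structure(
    list(profiles = profiles,
         burst = do.call(rbind, c(bursts, list(make.row.names = FALSE))),
         comparisons = comparisons,
         gcg_table = do.call(rbind, c(gcg_rows, list(make.row.names = FALSE))),
         f2 = f2_results,
         failures = if (length(failures)) do.call(rbind, failures)
                    else data.frame(stage = character(), key = character(),
                                    message = character(), stringsAsFactors = FALSE),
         metadata = list(
           seed = config$seed, n_starts = config$n_starts,
           config_hash = .relkin_hash(list(models = models, f2_pairs = f2_pairs,
                                           config = config)),
           version = as.character(utils::packageVersion("relkin")))),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d profile(s), seed %d, config %s, relkin %s\n",
              length(x$profiles), x$metadata$seed, x$metadata$config_hash,
              x$metadata$version))
  cat("\nBurst (experimental 24-h release):\n")
  print(x$burst, row.names = FALSE, digits = 4)
  cat("\nBiphasic (burst-corrected) parameter table:\n")
  tab <- x$gcg_table
  tab[3:11] <- lapply(tab[3:11], function(v) signif(v, 4))
  print(tab[c("assay", "analyte", "experimental_b", "b", "Y1", "k1",
              "Y2", "k2", "t2", "r2_adjusted", "converged")], row.names = FALSE)
  if (length(x$f2)) {
    cat("\nf2 similarity:\n")
    for (k in names(x$f2)) {
      r <- x$f2[[k]]
      if (!is.null(r)) cat(sprintf("  %s: f2 = %.2f (%s, n = %d)\n",
                                   k, r$f2, r$verdict, r$n_used))
    }
  }
  if (nrow(x$failures)) {
    cat("\nStage failures:\n"); print(x$failures, row.names = FALSE)
  }
  invisible(x)
}

#' Write the machine-readable part of a report bundle to JSON
#'
#' @param bundle A [characterize()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "report_bundle"))
  out <- list(
    metadata = bundle$metadata,
    burst = bundle$burst,
    gcg_table = bundle$gcg_table,
    ranking = lapply(bundle$comparisons, function(c)
      if (is.null(c)) NULL else c$ranking),
    f2 = lapply(bundle$f2, function(r)
      if (is.null(r)) NULL else r[c("f2", "n_used", "truncated_at", "verdict")]),
    failures = bundle$failures)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
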