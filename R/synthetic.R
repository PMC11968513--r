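#' Standard long-term release sampling schedule
#'
#' Sampling at 24 h, day 7, and then once a week until the end of the study
#' (no partial final week): the schedule used for multi-month microsphere
#' release assays.
#'
#' @param end_day Last study day (>= 7).
#' @return Numeric vector of sampling days, e.g. `c(1, 7, 14, ...)`.
#' @export
release_schedule <- function(end_day) {
  if (!is.numeric(end_day) || length(end_day) != 1L || end_day < 7) {
    stop("`end_day` must be >= 7", call. = FALSE)
  }
  c(1, seq(7, end_day, by = 7))
}

#' Reference biphasic parameter sets for PLGA microsphere release
#'
#' Published Gallagher-Corrigan/Gorrasi parameter estimates for the release
#' of ursodeoxycholic acid (UDCA), dexamethasone (DX) and GDNF from
#' single-, double- and tri-loaded PLGA (50:50) microspheres over a 91-day
#' assay, together with the model-free experimental 24-h burst fraction of
#' each profile. These seven curves span the parameter magnitudes the
#' fitting machinery must handle (rate constants from ~0.009 to
#' 0.41 per day, stage-2 centres from 30 to 81 days) and drive the
#' package's recovery tests.
#'
#' @return Named list keyed `"formulation:analyte"`; each entry has
#'   `formulation`, `analyte`, `experimental_b` (24-h released fraction)
#'   and `params` (a [gcg_params()] object).
#' @export
reference_gcg_params <- function() {
  rows <- list(
    list("UDCA-MSs",          "UDCA", 0.0458, 0.0408,  0.2000, 0.0087, 0.8550, 0.3760, 32.80),
    list("DX-UDCA-MSs",       "UDCA", 0.2100, 0.1442,  0.1264, 0.3027, 0.4866, 0.3498, 30.03),
    list("DX-UDCA-GDNF-MSs",  "UDCA", 0.1018, 0.0882,  0.1568, 0.0469, 0.9481, 0.2997, 30.37),
    list("DX-MSs",            "DX",   0.0468, 0.02982, 0.0468, 0.4090, 0.6986, 0.1337, 49.15),
    list("DX-UDCA-MSs",       "DX",   0.1891, 0.1436,  0.2225, 0.2284, 0.3442, 0.1661, 42.25),
    list("DX-UDCA-GDNF-MSs",  "DX",   0.1543, 0.1066,  0.3954, 0.1157, 0.3442, 0.1537, 46.71),
    list("DX-UDCA-GDNF-MSs",  "GDNF", 0.2993, 0.2648,  0.1524, 0.1185, 0.2688, 0.0885, 81.07)
  )
  out <- lapply(rows, function(r) {
    list(formulation = r[[1]], analyte = r[[2]], experimental_b = r[[3]],
         params = gcg_params(b = r[[4]], Y1 = r[[5]], k1 = r[[6]],
                             Y2 = r[[7]], k2 = r[[8]], t2 = r[[9]]))
  })
  stats::setNames(out, vapply(out, function(r)
    paste0(r$formulation, ":", r$analyte), character(1)))
}

#' Reference analyte loadings for the same formulations
#'
#' Measured payloads (amount of active per mg of microspheres) and
#' encapsulation efficiencies for the formulations of
#' [reference_gcg_params()]. GDNF is carried in ng/mg — three orders of
#' magnitude below the small molecules — to exercise per-analyte unit
#' handling.
#'
#' @return Named list keyed `"formulation:analyte"` of [analyte_loading()].
#' @export
reference_loadings <- function() {
  rows <- list(
    list("UDCA-MSs",         "UDCA", 55.55,  "ug/mg", 0.5979),
    list("DX-UDCA-MSs",      "UDCA", 49.52,  "ug/mg", 0.6515),
    list("DX-UDCA-MSs",      "DX",   95.79,  "ug/mg", 0.8612),
    list("DX-MSs",           "DX",   103.74, "ug/mg", 0.7936),
    list("DX-UDCA-GDNF-MSs", "UDCA", 52.65,  "ug/mg", 0.6427),
    list("DX-UDCA-GDNF-MSs", "DX",   101.04, "ug/mg", 0.8436),
    list("DX-UDCA-GDNF-MSs", "GDNF", 19.83,  "ng/mg", 0.5160)
  )
  out <- lapply(rows, function(r)
    analyte_loading(r[[2]], r[[3]], unit = r[[4]], entrapment_fraction = r[[5]]))
  stats::setNames(out, vapply(rows, function(r)
    paste0(r[[1]], ":", r[[2]]), character(1)))
}

#' Configuration for a simulated release assay
#'
#' Describes the "true" world a simulated assay is drawn from: the
#' generating kinetic model and parameters per analyte, the assay geometry
#' (defaults: 5 mg of microspheres in 2 mL of medium, triplicate vials,
#' sampling at 24 h then weekly to day 91), and the measurement noise.
#'
#' @param params Named list: analyte name -> generating parameter list
#'   (e.g. a [gcg_params()]).
#' @param loadings List of [analyte_loading()], one per analyte in `params`.
#' @param model Generating model name (default the burst-corrected biphasic
#'   model).
#' @param sample_mass_mg,medium_volume_ml Assay geometry.
#' @param schedule_days Strictly increasing sampling times.
#' @param n_replicates Number of replicate vials.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise applied to each per-interval released amount
#'   (default 0.02, a low-noise assay).
#' @param seed Mandatory integer seed; identical seeds give identical assays.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(params, loadings,
                             model = "gallagher_corrigan_gorrasi",
                             sample_mass_mg = 5, medium_volume_ml = 2,
                             schedule_days = release_schedule(91),
                             n_replicates = 3, noise_cv = 0.02, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (any(diff(schedule_days) <= 0) || any(schedule_days <= 0)) {
    stop("`schedule_days` must be strictly increasing and > 0", call. = FALSE)
  }
  if (inherits(loadings, "analyte_loading")) loadings <- list(loadings)
  names(loadings) <- vapply(loadings, `[[`, character(1), "analyte")
  if (!all(names(params) %in% names(loadings))) {
    stop("every analyte in `params` needs a loading", call. = FALSE)
  }
  spec <- model_spec(model)
  for (a in names(params)) {
    pv <- unlist(params[[a]][spec$params])
    if (length(pv) != spec$p || any(is.na(pv))) {
      stop(sprintf("analyte %s: parameters must be named %s", a,
                   paste(spec$params, collapse = ", ")), call. = FALSE)
    }
    lo <- spec$lower; hi <- spec$upper
    if (any(pv < lo - 1e-12) || any(pv > hi + 1e-12)) {
      stop(sprintf("analyte %s: parameters outside model bounds", a), call. = FALSE)
    }
  }
  structure(
    list(model = model, params = params, loadings = loadings,
         sample_mass_mg = sample_mass_mg, medium_volume_ml = medium_volume_ml,
         schedule_days = as.numeric(schedule_days),
         n_replicates = as.integer(n_replicates),
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a replicate-level release assay
#'
#' For each replicate and analyte the true cumulative released fraction
#' `F(t_k)` under the generating model is converted to per-interval released
#' amounts `dA_k = (F(t_k) - F(t_(k-1))) * loading * mass` (with
#' `F(t_0) = 0`: everything released before the first sampling, including
#' the burst, appears in the first supernatant). Each increment is
#' perturbed multiplicatively with the configured coefficient of variation,
#' floored at zero (so replicate cumulative series stay non-decreasing),
#' and expressed as a supernatant concentration `dA_k / volume`. By
#' construction [cumulative_from_samples()] inverts the simulation exactly
#' at `noise_cv = 0`.
#'
#' @param config A [synthetic_config()].
#' @return A [release_assay()].
#' @export
generate_assay <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- model_spec(config$model)
  t <- config$schedule_days
  set.seed(config$seed)
  rows <- list()
  for (a in names(config$params)) {
    Fv <- predict_release(spec, config$params[[a]][spec$params], t)
    dF <- diff(c(0, Fv))
    load <- config$loadings[[a]]$loading_per_mg
    dA <- dF * load * config$sample_mass_mg
    for (r in seq_len(config$n_replicates)) {
      noisy <- if (config$noise_cv > 0) {
        pmax(0, dA * (1 + config$noise_cv * stats::rnorm(length(dA))))
      } else dA
      rows[[length(rows) + 1L]] <- data.frame(
        time_days = t, replicate = r, analyte = a,
        concentration = noisy / config$medium_volume_ml,
        stringsAsFactors = FALSE)
    }
  }
  release_assay(config$sample_mass_mg, config$medium_volume_ml,
                config$loadings[names(config$params)],
                do.call(rbind, rows))
}
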