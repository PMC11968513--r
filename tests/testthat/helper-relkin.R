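# shared fixture builders -------------------------------------------------

toy_loading <- function(analyte = "DX", loading = 100, unit = "ug/mg") {
  analyte_loading(analyte, loading, unit = unit)
}

# small hand-specified assay: one analyte, concentrations per replicate
toy_assay <- function(times = c(1, 7, 14), conc = list(c(1, 2, 3)),
                      analyte = "DX", loading = 100,
                      mass = 5, volume = 2) {
  rows <- do.call(rbind, lapply(seq_along(conc), function(r) {
    data.frame(time_days = times, replicate = r, analyte = analyte,
               concentration = conc[[r]], stringsAsFactors = FALSE)
  }))
  release_assay(mass, volume, toy_loading(analyte, loading), rows)
}

# random assay used by round-trip property tests
random_assay <- function(seed) {
  set.seed(seed)
  times <- sort(sample(seq(1, 60), sample(3:8, 1)))
  analytes <- paste0("A", seq_len(sample(1:3, 1)))
  n_rep <- sample(1:4, 1)
  loadings <- lapply(analytes, function(a)
    analyte_loading(a, runif(1, 10, 200),
                    unit = sample(c("ug/mg", "ng/mg"), 1),
                    entrapment_fraction = runif(1, 0.4, 1.1)))
  rows <- expand.grid(time_days = times, replicate = seq_len(n_rep),
                      analyte = analytes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$concentration <- rexp(nrow(rows), rate = 0.5)
  rows$concentration[sample(nrow(rows), size = nrow(rows) %/% 10)] <- NA
  release_assay(5, 2, loadings, rows)
}

# reference row + matching loading, keyed "formulation:analyte"
ref_case <- function(key) {
  r <- reference_gcg_params()[[key]]
  list(row = r, loading = reference_loadings()[[key]])
}

# simulate one reference row into a cumulative profile
ref_profile <- function(key, noise_cv = 0, seed = 1, end_day = 91,
                        n_replicates = 3) {
  rc <- ref_case(key)
  cfg <- synthetic_config(
    params = stats::setNames(list(rc$row$params), rc$row$analyte),
    loadings = list(rc$loading), noise_cv = noise_cv, seed = seed,
    schedule_days = release_schedule(end_day), n_replicates = n_replicates)
  cumulative_from_samples(generate_assay(cfg), rc$row$analyte)
}
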