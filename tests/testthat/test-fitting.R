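test_that("adjusted_r2 follows its definition and contract", {
  expect_equal(adjusted_r2(1, 10, 3), 1)
  expect_equal(adjusted_r2(0.99, 10, 6), 0.9775)            # 1 - (9/4) * 0.01
  expect_equal(adjusted_r2(0.995, 15, 6), 1 - (14 / 9) * 0.005)
  expect_error(adjusted_r2(0.9, 6, 6), "n <= p")
  expect_error(adjusted_r2(0.9, 5, 6), "n <= p")
  expect_error(adjusted_r2(1.1, 10, 2), "<= 1")
  # penalty is monotone in p at fixed r2, n
  vals <- sapply(1:8, function(p) adjusted_r2(0.95, 10, p))
  expect_true(all(diff(vals) < 0))
})

test_that("an exact zero-order line is fitted exactly", {
  t <- release_schedule(91)
  prof <- profile_from_fraction(t, 0.01 * t)
  fit <- fit_model(prof, "zero_order", fit_config(seed = 1, n_starts = 8))
  expect_equal(unname(fit$params["k"]), 0.01, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("noiseless biphasic curves are recovered from the 91-day schedule", {
  # stage-2 centre of the single-loaded dexamethasone reference row
  prof <- ref_profile("DX-MSs:DX", noise_cv = 0, seed = 2)
  fit <- fit_model(prof, "gallagher_corrigan_gorrasi", fit_config(seed = 4))
  expect_equal(unname(fit$params["t2"]), 49.15, tolerance = 0.01)
  truth <- unlist(ref_case("DX-MSs:DX")$row$params)
  expect_lt(max(abs(fit$params[names(truth)] - truth) / truth), 0.01)
})

test_that("random valid parameter draws are self-recovered within 1%", {
  # spec'd at 100 draws; run 40 here to stay inside the suite's time budget
  set.seed(42)
  t <- release_schedule(91)
  for (i in 1:40) {
    repeat {
      p <- list(b = runif(1, 0, 0.3), Y1 = runif(1, 0.05, 0.4),
                k1 = runif(1, 0.01, 0.5), Y2 = runif(1, 0.1, 0.9),
                k2 = runif(1, 0.05, 0.5), t2 = runif(1, 15, 80))
      if (p$b + p$Y1 + p$Y2 <= 1.15) break
    }
    prof <- profile_from_fraction(t, gcg_predict(p, t))
    fit <- fit_model(prof, "gallagher_corrigan_gorrasi", fit_config(seed = i))
    rel <- abs(fit$params[names(p)] - unlist(p)) / abs(unlist(p))
    expect_lt(max(rel), 0.01)
  }
})

test_that("fits are bit-identical under the same seed", {
  prof <- ref_profile("DX-UDCA-MSs:DX", noise_cv = 0.02, seed = 9)
  f1 <- fit_model(prof, "gallagher_corrigan_gorrasi", fit_config(seed = 123))
  f2 <- fit_model(prof, "gallagher_corrigan_gorrasi", fit_config(seed = 123))
  expect_identical(f1, f2)
})

test_that("fit_model enforces its preconditions", {
  prof <- profile_from_fraction(c(1, 7, 14, 21, 28), rep(0.1, 5) * 1:5)
  expect_error(fit_model(prof, "gallagher_corrigan_gorrasi"),
               "more than p = 6")
  bad <- profile_from_fraction(c(1, 7, 14), c(0.1, 0.2, 0.3))
  bad$fraction_released[2] <- Inf
  expect_error(fit_model(bad, "zero_order"), "finite")
})

test_that("segmented fits rebase each step and pool goodness of fit", {
  # exact two-slope piecewise-linear profile: slopes recovered exactly
  t <- c(1:6, 8, 10, 12, 14)
  y <- ifelse(t <= 6, 0.02 * t, 0.02 * 6 + 0.06 * (t - 6))
  prof <- profile_from_fraction(t, y)
  seg <- fit_segmented(prof, "zero_order", breakpoints = 6,
                       config = fit_config(seed = 1, n_starts = 8))
  expect_length(seg$segments, 2L)
  expect_equal(unname(seg$segments[[1]]$params["k"]), 0.02, tolerance = 1e-7)
  expect_equal(unname(seg$segments[[2]]$params["k"]), 0.06, tolerance = 1e-7)
  expect_lt(seg$pooled$sse, 1e-12)
  expect_equal(seg$pooled$r2, 1, tolerance = 1e-9)

  # 2 breakpoints on a 14-point profile, p = 2 per segment: 3 results + pooled r2
  t14 <- release_schedule(91)
  prof14 <- profile_from_fraction(t14, gcg_predict(
    list(b = 0.1, Y1 = 0.2, k1 = 0.2, Y2 = 0.5, k2 = 0.2, t2 = 45), t14))
  seg3 <- fit_segmented(prof14, "korsmeyer_peppas", breakpoints = c(21, 56),
                        config = fit_config(seed = 2, n_starts = 8))
  expect_length(seg3$segments, 3L)
  expect_true(is.numeric(seg3$pooled$r2) && seg3$pooled$r2 <= 1)

  expect_error(fit_segmented(prof14, "korsmeyer_peppas", c(3, 5, 7)),
               "1 or 2 breakpoints")
  expect_error(fit_segmented(prof14, "korkmeyer", 21), "unknown model")
  expect_error(fit_segmented(prof14, "korsmeyer_peppas", 91), "strictly inside")
  expect_error(fit_segmented(prof14, "gallagher_corrigan_gorrasi", 7),
               "segment 1")
})

test_that("segmenting rescues a single-mechanism model on a sigmoid", {
  prof <- ref_profile("DX-MSs:DX", noise_cv = 0, seed = 6)
  whole <- fit_model(prof, "higuchi", fit_config(seed = 3, n_starts = 8))
  seg <- fit_segmented(prof, "higuchi", breakpoints = c(35, 63),
                       config = fit_config(seed = 3, n_starts = 8))
  expect_lt(seg$pooled$sse, whole$sse)
})

test_that("compare_models ranks by adjusted R2 with the stated tie-breaks", {
  # exact line: zero_order and korsmeyer_peppas(n -> 1) both reach R2 = 1;
  # the tie goes to the model with fewer parameters
  t <- release_schedule(70)
  prof <- profile_from_fraction(t, 0.004 * t)
  cmp <- compare_models(prof, c("zero_order", "korsmeyer_peppas", "higuchi"),
                        fit_config(seed = 5, n_starts = 8))
  expect_equal(cmp$selected, "zero_order")
  expect_equal(cmp$ranking$model[1:2], c("zero_order", "korsmeyer_peppas"))
  expect_true(all(diff(ifelse(is.finite(cmp$ranking$r2_adjusted),
                              cmp$ranking$r2_adjusted, -Inf)) <= 1e-12))

  # a model that cannot be fitted is kept, flagged, and ranked last
  short <- profile_from_fraction(c(1, 7, 14, 21, 28, 35),
                                 c(0.05, 0.1, 0.2, 0.3, 0.33, 0.35))
  cmp2 <- compare_models(short,
                         c("zero_order", "higuchi", "gallagher_corrigan_gorrasi"),
                         fit_config(seed = 5, n_starts = 8))
  last <- cmp2$fits[[length(cmp2$fits)]]
  expect_equal(last$model, "gallagher_corrigan_gorrasi")
  expect_false(last$converged)
  expect_error(compare_models(short, "zero_order"), "at least 2")
})

test_that("the generating biphasic model wins the catalog on its own data", {
  # selection-consistency: 20 seeded replicates of the co-loaded UDCA row
  rc <- ref_case("DX-UDCA-MSs:UDCA")
  for (s in 1:20) {
    cfg <- synthetic_config(params = list(UDCA = rc$row$params),
                            loadings = list(rc$loading),
                            noise_cv = 0.02, seed = 100 + s)
    prof <- cumulative_from_samples(generate_assay(cfg), "UDCA")
    cmp <- compare_models(prof, config = fit_config(seed = s))
    expect_equal(cmp$selected, "gallagher_corrigan_gorrasi")
  }
})
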