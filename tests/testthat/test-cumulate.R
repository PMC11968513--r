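test_that("cumulative amounts follow the sample-and-replace mass balance", {
  a <- toy_assay(times = c(1, 7, 14), conc = list(c(1, 2, 3)))
  prof <- cumulative_from_samples(a, "DX")
  # (2 + 4 + 6) ug running sum over 5 mg
  expect_equal(prof$mean_cumulative, c(0.4, 1.2, 2.4))
  expect_equal(prof$fraction_released, c(0.4, 1.2, 2.4) / 100)

  z <- toy_assay(conc = list(c(0, 0, 0), c(0, 0, 0)))
  pz <- cumulative_from_samples(z, "DX")
  expect_equal(pz$mean_cumulative, c(0, 0, 0))
  expect_equal(pz$sd_cumulative, c(0, 0, 0))

  expect_error(cumulative_from_samples(a, "UDCA"), "not present")
})

test_that("cumulate inverts the noiseless generator to 1e-9", {
  for (key in c("UDCA-MSs:UDCA", "DX-UDCA-GDNF-MSs:GDNF")) {
    rc <- ref_case(key)
    prof <- ref_profile(key, noise_cv = 0, seed = 3)
    truth <- gcg_predict(rc$row$params, prof$times_days)
    expect_equal(prof$fraction_released, truth, tolerance = 1e-9)
    expect_equal(prof$sd_cumulative, rep(0, length(truth)), tolerance = 1e-12)
  }
})

test_that("non-negative concentrations give non-decreasing replicate series", {
  for (seed in 1:15) {
    set.seed(seed)
    a <- toy_assay(times = cumsum(runif(8, 0.5, 9)),
                   conc = lapply(1:3, function(i) rexp(8)))
    prof <- cumulative_from_samples(a, "DX")
    for (r in seq_len(nrow(prof$per_replicate))) {
      expect_true(all(diff(prof$per_replicate[r, ]) >= -1e-12))
    }
  }
})

test_that("profile is linear in concentration and exact in total mass", {
  a1 <- toy_assay(conc = list(c(1, 2, 3), c(2, 1, 4)))
  a3 <- toy_assay(conc = list(3 * c(1, 2, 3), 3 * c(2, 1, 4)))
  p1 <- cumulative_from_samples(a1, "DX")
  p3 <- cumulative_from_samples(a3, "DX")
  expect_equal(p3$mean_cumulative, 3 * p1$mean_cumulative)
  expect_equal(p3$sd_cumulative, 3 * p1$sd_cumulative)
  # total equals sum(C_i * V) / mass exactly, per replicate
  expect_equal(p1$per_replicate[, 3],
               c(`1` = sum(c(1, 2, 3)) * 2 / 5, `2` = sum(c(2, 1, 4)) * 2 / 5))
})

test_that("missing cells blank later sums for that replicate only", {
  m <- rbind(
    data.frame(time_days = c(1, 7, 14), replicate = 1, analyte = "DX",
               concentration = c(1, 2, 3)),
    data.frame(time_days = c(1, 14), replicate = 2, analyte = "DX",
               concentration = c(1, 3)))   # rep 2 lost its day-7 sample
  a <- release_assay(5, 2, toy_loading(), m)
  prof <- cumulative_from_samples(a, "DX")
  expect_equal(unname(prof$per_replicate[1, ]), c(0.4, 1.2, 2.4))
  expect_equal(unname(prof$per_replicate[2, ]), c(0.4, NA, NA))
  expect_equal(prof$mean_cumulative, c(0.4, 1.2, 2.4))  # rep-1 carries the mean
})

test_that("experimental burst reads the sampling nearest 24 h", {
  a <- toy_assay(times = c(1, 7, 14), conc = list(c(1, 2, 3)), loading = 100)
  # fraction at t=1 is 0.4/100; scale concentrations for a 0.21 burst
  a21 <- toy_assay(times = c(1, 7, 14), conc = list(c(52.5, 2, 3)), loading = 100)
  b <- experimental_burst(cumulative_from_samples(a21, "DX"))
  expect_equal(b$burst_fraction, 0.21)
  expect_equal(b$time_days, 1)

  z <- experimental_burst(cumulative_from_samples(
    toy_assay(conc = list(c(0, 0, 0))), "DX"))
  expect_equal(z$burst_fraction, 0)
  expect_equal(z$burst_amount_per_mg, 0)

  late <- toy_assay(times = c(7, 14, 21), conc = list(c(1, 2, 3)))
  expect_error(experimental_burst(cumulative_from_samples(late, "DX")),
               "burst undefined")
})

test_that("interval release rate is the (interpolated) mean slope", {
  a <- toy_assay(times = c(1, 7), conc = list(c(1, 2)))
  prof <- cumulative_from_samples(a, "DX")   # 0.4, 1.2 ug/mg
  expect_equal(interval_release_rate(prof, 1, 7), 0.8 / 6)

  const <- cumulative_from_samples(
    toy_assay(times = c(1, 7, 14), conc = list(c(1, 0, 0))), "DX")
  expect_equal(interval_release_rate(const, 1, 14), 0)

  # zero-order simulation: rate k on any sub-interval
  k <- 0.008
  t <- release_schedule(49)
  cfg <- synthetic_config(params = list(DX = list(k = k)),
                          loadings = list(toy_loading(loading = 50)),
                          model = "zero_order", schedule_days = t,
                          noise_cv = 0, seed = 5)
  prof0 <- cumulative_from_samples(generate_assay(cfg), "DX")
  for (iv in list(c(1, 49), c(7, 21), c(10, 30))) {
    expect_equal(interval_release_rate(prof0, iv[1], iv[2]), k * 50,
                 tolerance = 1e-9)
  }

  expect_error(interval_release_rate(prof, 0.5, 7), "outside observed span")
  expect_error(interval_release_rate(prof, 7, 7), "t_start")
})
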