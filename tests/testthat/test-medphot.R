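test_that("accuracy is the deviation around the population median", {
  r <- accuracy_deviation(c(0.09, 0.10, 0.11))
  expect_equal(r$deviation_pct, c(10, 0, 10))
  expect_equal(r$median_deviation_pct, 10)
  expect_equal(accuracy_deviation(rep(0.07, 5))$median_deviation_pct, 0)
  # ratio definition: invariant under common scaling
  expect_equal(accuracy_deviation(3 * c(0.09, 0.10, 0.11))$deviation_pct,
               c(10, 0, 10))
  expect_error(accuracy_deviation(c(0.1, 0.2)), "3")
  expect_error(accuracy_deviation(c(-1, 0, 1)), "median")
})

test_that("linearity deviation matches a closed-form regression oracle", {
  # an exactly affine kit is perfectly linear
  lin <- linearity_fom(synthetic_kit(mua_gain = 1.1, mua_offset = 0.01,
                                     mus_gain = 0.9, mus_offset = 0.5))
  expect_equal(unname(lin), c(0, 0), tolerance = 1e-10)

  # single series vs the independent OLS oracle
  kit <- data.frame(label = c("X1", "X2", "X3"),
                    nominal_mua = c(0.05, 0.10, 0.15),
                    nominal_musp = 10,
                    mua = c(0.050, 0.110, 0.150),
                    musp = c(10, 10, 10))
  o <- ols_oracle(kit$nominal_mua, kit$mua)
  exp_dev <- median(abs(kit$mua - o$fitted) / o$fitted * 100)
  got <- suppressWarnings(
    median(nirsperf:::.series_deviations(kit, "nominal_mua", "mua",
                                         "nominal_musp")))
  expect_equal(got, exp_dev)

  # row order is irrelevant
  k1 <- synthetic_kit(couple_mua_from_mus = 2e-4)
  k2 <- k1[sample(nrow(k1)), ]
  expect_equal(linearity_fom(k2), linearity_fom(k1))
})

test_that("crosstalk coefficients follow the cause->effect rescaling", {
  # no coupling: retrieved mua constant across scattering series
  ct0 <- crosstalk_fom(synthetic_kit())
  expect_equal(ct0$F_mus_to_mua, 0, tolerance = 1e-12)
  expect_equal(ct0$F_mua_to_mus, 0, tolerance = 1e-12)

  # injected coupling: mua <- mua + 0.001 (musp - 10)
  ct <- crosstalk_fom(synthetic_kit(couple_mua_from_mus = 0.001))
  expect_equal(ct$S_mua_given_mus, 0.001, tolerance = 1e-10)
  expect_equal(ct$F_mus_to_mua, 0.001 * 10 / 0.1, tolerance = 1e-10)

  # relative effect of a relative cause: F = 0.13, 10% cause -> 1.3% effect
  expect_identical(crosstalk_effect(0.13, 10), 1.3)
})

test_that("stability range and drift match their arithmetic definitions", {
  fm0 <- suppressWarnings(stability_fom(seq(0, 50, 10), rep(0.1, 6)))
  expect_equal(unname(fm0), c(0, 0))
  expect_warning(stability_fom(seq(0, 55, 5), rep(0.1, 12)), "60 min")

  # linear ramp 0.100 -> 0.102 over 100 min: mean 0.101
  tm <- seq(0, 100, length.out = 11)
  vals <- seq(0.100, 0.102, length.out = 11)
  fm <- stability_fom(tm, vals)
  expect_equal(fm[["range_pct"]], 0.002 / 0.101 * 100, tolerance = 1e-10)
  expect_equal(fm[["drift_pct_per_min"]], 2e-5 / 0.101 * 100,
               tolerance = 1e-10)
  # time reversal flips neither magnitude
  fr <- stability_fom(rev(tm), vals)
  expect_equal(fr, fm)

  expect_equal(drift_projection(0.03, 100), 3)
  expect_equal(drift_projection(5, 0), 0)
  expect_equal(drift_projection(0.02, 30) + drift_projection(0.02, 70),
               drift_projection(0.02, 100))
})

test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(cv(c(9, 10, 11)), 10)
  expect_equal(cv(rep(4, 10)), 0)
  expect_equal(cv(c(9, 10, 11) * 1e6), 10)
  expect_equal(reproducibility_fom(c(0.10, 0.10, 0.11)),
               sd(c(0.10, 0.10, 0.11)) / mean(c(0.10, 0.10, 0.11)) * 100)
  expect_equal(reproducibility_fom(c(0.10, 0.10, 0.11)), 5.587, tolerance = 1e-3)
  expect_equal(reproducibility_fom(c(0.11, 0.10, 0.10)),
               reproducibility_fom(c(0.10, 0.10, 0.11)))
})

test_that("noise FOM inverts the fitted log-log CV curve", {
  # closed-form oracle: CV = 2% sqrt(1e5 / N) crosses 1% at N = 4e5
  N <- c(1e4, 1e5, 1e6)
  cvs <- 2 * sqrt(1e5 / N)
  nf <- noise_fom(N, cv_pct = cvs)
  expect_equal(as.numeric(nf), 4e5, tolerance = 1e-9)
  expect_equal(attr(nf, "slope"), -0.5, tolerance = 1e-12)

  # fixed point: levels already on a line through (N*, 1%)
  nf2 <- noise_fom(N, cv_pct = sqrt(2e5 / N))
  expect_equal(as.numeric(nf2), 2e5, tolerance = 1e-9)

  # reordering levels changes nothing
  o <- c(3, 1, 2)
  expect_equal(as.numeric(noise_fom(N[o], cv_pct = cvs[o])), 4e5,
               tolerance = 1e-9)

  # estimates route: CV computed internally per level
  est <- list(c(9, 10, 11), c(9.7, 10, 10.3), c(9.9, 10, 10.1))
  expect_silent(noise_fom(N, est))
  expect_error(noise_fom(N, cv_pct = rev(cvs)), "decrease")
  expect_error(noise_fom(c(1e4, 2e4, 3e4), cv_pct = cvs), "decade")
})
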