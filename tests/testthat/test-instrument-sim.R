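test_that("virtual phantom kit covers the full grid with anchored labels", {
  kit <- medphot_kit()
  expect_equal(nrow(kit), 32)
  expect_equal(kit$mua[kit$label == "B2"], 0.05)
  expect_equal(kit$musp[kit$label == "B2"], 10)
  expect_equal(kit$mua[kit$label == "B3"], 0.1)
  expect_equal(kit$musp[kit$label == "B3"], 10)
  expect_equal(kit$mua[kit$label == "A1"], 0)
  expect_equal(kit$musp[kit$label == "A1"], 5)
  expect_setequal(unique(kit$mua), seq(0, 0.35, by = 0.05))
  expect_setequal(unique(kit$musp), c(5, 10, 15, 20))
})

test_that("synthesized IRF has the requested width, area and tail weight", {
  inst <- instrument_model(irf = irf_model(fwhm_ps = 200), dark_rate_cps = 0)
  irf <- make_irf(inst, total_counts = 1e6, sample = FALSE)
  expect_equal(irf_fwhm(irf), 200, tolerance = inst$channel_width_ps / 200)
  expect_equal(sum(irf$expectation), 1e6, tolerance = 1e-3)

  # first-moment oracle: an exponential tail delays the mean arrival time
  inst_t <- instrument_model(irf = irf_model(fwhm_ps = 200,
                                             tail_fraction = 0.3,
                                             tail_tau_ps = 500),
                             dark_rate_cps = 0)
  irf_t <- make_irf(inst_t, sample = FALSE)
  tt <- dtof_times(irf_t)
  mean_mix <- sum(tt * irf_t$expectation) / sum(irf_t$expectation)
  mean_gauss <- sum(tt * irf$expectation) / sum(irf$expectation)
  # independent oracle: mixture mean = (1-f) t0 + f (t0 + tau)
  expect_equal(mean_mix - mean_gauss, 0.3 * 500, tolerance = 0.02)
  expect_gt(mean_mix, mean_gauss)

  expect_error(make_irf(instrument_model(irf = irf_model(fwhm_ps = 2))),
               "channel width")
})

test_that("DTOF synthesis is seed-reproducible with Poisson statistics", {
  inst <- typical_instrument(dark_rate_cps = 500)
  p <- standard_props()
  a <- synthesize_dtof(p, inst, signal_counts = 2e5, seed = 7)
  b <- synthesize_dtof(p, inst, signal_counts = 2e5, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_false(identical(
    a$counts, synthesize_dtof(p, inst, signal_counts = 2e5, seed = 8)$counts))

  # mean total counts over replicates vs the Poisson mean/variance identity
  mu_tot <- sum(a$expectation)
  tot <- replicate(60, sum(synthesize_dtof(p, inst, signal_counts = 2e5)$counts))
  expect_lt(abs(mean(tot) - mu_tot), 3 * sqrt(mu_tot / 60))
  expect_equal(mu_tot, 2e5 + 500 / inst$n_channels * inst$n_channels,
               tolerance = 1e-6)
})

test_that("delta IRF makes expectations proportional to the forward model", {
  inst <- ideal_instrument()
  p <- standard_props()
  d <- synthesize_dtof(p, inst, geom = geometry(rho_mm = 30),
                       signal_counts = 1e6, sample = FALSE)
  i0 <- which.max(make_irf(inst, sample = FALSE)$counts)
  tc <- dtof_times(d)
  shift <- (i0 - 1) * inst$channel_width_ps
  idx <- which(tc - shift > 0 & d$expectation > max(d$expectation) * 1e-8)
  fwd <- td_reflectance(30, tc[idx] - shift, p, geometry(rho_mm = 30))
  ratio <- d$expectation[idx] / fwd
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("DNL and dark fixtures reproduce their injected truth", {
  n <- 256
  pat <- 1 + 0.1 * sin(2 * pi * 4 * seq_len(n) / n)
  pat <- pat / mean(pat)
  inst <- instrument_model(n_channels = n, dnl_pattern = pat,
                           dark_rate_cps = 0)
  m <- synthesize_dnl_measurement(inst, counts_per_channel = 1e6,
                                  sample = FALSE)
  expect_equal(m$expectation / 1e6, pat)  # expectation exactly proportional
  expect_equal(dnl_eps(synthesize_dnl_measurement(inst, 1e6, seed = 3),
                       edge_frac = 0),
               0.2, tolerance = 0.05)

  # flat pattern: estimator bounded by Poisson sampling extremes
  flat <- instrument_model(n_channels = n, dark_rate_cps = 0)
  eps <- dnl_eps(synthesize_dnl_measurement(flat, 1e5, seed = 4))
  expect_lt(eps, 10 * sqrt(1 / 1e5))

  drk <- synthesize_dark(instrument_model(dark_rate_cps = 2000), tmeas_s = 5,
                         seed = 5)
  expect_equal(sum(drk$counts), 2000 * 5, tolerance = 0.05)
  expect_equal(drk$kind, "dark")
  expect_true(all(synthesize_dark(instrument_model(dark_rate_cps = 0),
                                  tmeas_s = 1)$counts == 0))
})

test_that("stability series applies drift linearly and keeps its schedule", {
  inst <- typical_instrument()
  p <- optical_props(0.05, 10)
  expect_warning(
    s_short <- synthesize_stability_series(p, inst, duration_min = 10,
                                           period_s = 300, seed = 1),
    "deviation")
  expect_length(s_short$dtofs, floor(10 / 5) + 1)

  # timing drift must surface as a monotone trend in retrieved absorption
  inst_d <- instrument_model(irf = irf_model(fwhm_ps = 300),
                             dark_rate_cps = 0, drift_t0_ps_per_min = 1)
  irf <- make_irf(inst_d, sample = FALSE)
  ser <- synthesize_stability_series(p, inst_d, duration_min = 60,
                                     period_s = 900, signal_counts = 1e6,
                                     seed = 2)
  mua <- vapply(ser$dtofs, function(d)
    coef(fit_optical_properties(d, irf, fit_t0 = FALSE))[["mua"]], numeric(1))
  expect_gt(abs(mua[length(mua)] - mua[1]), 5 * sd(diff(mua)) / sqrt(2))
  expect_gt(abs(cor(ser$time_min, mua)), 0.9)
})

test_that("noise series and sessions have the declared structure", {
  inst <- typical_instrument()
  p <- optical_props(0.05, 10)
  ns <- synthesize_noise_series(p, inst, count_levels = c(1e4, 1e5),
                                n_reps = 3, seed = 6)
  expect_length(ns$dtofs, 2)
  expect_length(ns$dtofs[[1]], 3)
  tot <- vapply(ns$dtofs, function(l) mean(vapply(l, function(d)
    sum(d$counts), numeric(1))), numeric(1))
  expect_true(all(diff(tot) > 0))        # totals ordered as count levels
  expect_false(identical(ns$dtofs[[1]][[1]]$counts,
                         ns$dtofs[[1]][[2]]$counts))

  ss <- synthesize_sessions(p, inst, n_sessions = 3, n_reps = 2, seed = 7)
  expect_length(ss$sessions, 3)
  expect_length(ss$sessions[[1]], 2)
})

test_that("responsivity fixture round-trips through the defining formula", {
  inst <- typical_instrument()
  ri <- synthesize_responsivity_measurement(inst, kappa_p = 1e16,
                                            Pin_W = 1e-3, tmeas_s = 1,
                                            true_responsivity = 1e-8,
                                            seed = 8)
  lam <- 1e-8 * 1 * 1e16 * 1e-3
  expect_equal(responsivity(ri), 1e-8, tolerance = 4 / sqrt(lam))
  # Ntot scales with tmeas in expectation
  ri10 <- synthesize_responsivity_measurement(inst, 1e16, 1e-3, 10, 1e-8,
                                              seed = 9)
  expect_equal(ri10$Ntot / ri$Ntot, 10, tolerance = 0.2)
  expect_error(synthesize_responsivity_measurement(inst, 1e16, 0, 1, 1e-8),
               "Pin_W")
})
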