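test_that("background subtraction recovers known flat backgrounds", {
  # zero-background input is unchanged (delta IRF: pre-peak exactly empty)
  dz <- synthesize_dtof(standard_props(), ideal_instrument(),
                        signal_counts = 1e6, sample = FALSE)
  d0 <- subtract_background(dz)
  expect_equal(d0$counts, dz$counts, tolerance = 1e-10)

  inst <- typical_instrument()
  d <- synthesize_dtof(standard_props(), inst, signal_counts = 1e6,
                       sample = FALSE)
  # uniform +k counts/channel: pre-peak estimate close to k
  k <- 50
  dk <- d
  dk$counts <- d$counts + k
  dbg <- subtract_background(dk)
  expect_equal(attr(dbg, "background"), k, tolerance = 5 * sqrt(k) / k)

  # dark-paired strategy removes exactly the dark expectation (in mean)
  inst_d <- typical_instrument(dark_rate_cps = 5000)
  dd <- synthesize_dtof(standard_props(), inst_d, signal_counts = 1e5,
                        seed = 1)
  drk <- synthesize_dark(inst_d, tmeas_s = 100, seed = 2)
  sub <- subtract_background(dd, "dark", dark = drk)
  expect_equal(attr(sub, "background"), 5000 / inst_d$n_channels,
               tolerance = 0.05)
  expect_true(all(sub$counts >= 0))
})

test_that("noise-free self-consistency recovers the generating properties", {
  inst <- ideal_instrument()
  irf <- make_irf(inst, sample = FALSE)
  d <- synthesize_dtof(standard_props(), inst, signal_counts = 1e6,
                       sample = FALSE)
  fit <- fit_optical_properties(d, irf)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["mua"]], 0.1, tolerance = 0.01)
  expect_equal(coef(fit)[["musp"]], 10, tolerance = 0.01)
})

test_that("the fit is scale invariant: amplitude absorbs total counts", {
  inst <- typical_instrument()
  irf <- make_irf(inst, sample = FALSE)
  d1 <- synthesize_dtof(standard_props(), inst, signal_counts = 1e6,
                        sample = FALSE)
  d2 <- d1
  d2$counts <- d1$counts * 2
  f1 <- fit_optical_properties(d1, irf)
  f2 <- fit_optical_properties(d2, irf)
  expect_equal(coef(f2)[["mua"]], coef(f1)[["mua"]], tolerance = 1e-4)
  expect_equal(coef(f2)[["musp"]], coef(f1)[["musp"]], tolerance = 1e-4)
  expect_equal(f2$amplitude / f1$amplitude, 2, tolerance = 1e-3)
})

test_that("Poisson replicates with a realistic IRF are recovered accurately", {
  inst <- typical_instrument()
  irf <- make_irf(inst, seed = 20)
  est <- t(vapply(1:5, function(i) {
    d <- synthesize_dtof(standard_props(), inst, signal_counts = 1e6,
                         seed = 100 + i)
    coef(fit_optical_properties(d, irf))[c("mua", "musp")]
  }, numeric(2)))
  expect_lt(median(abs(est[, 1] - 0.1) / 0.1), 0.05)
  expect_lt(median(abs(est[, 2] - 10) / 10), 0.05)
})

test_that("fit interface enforces its preconditions and reports its state", {
  inst <- typical_instrument()
  irf <- make_irf(inst, seed = 21)
  d <- synthesize_dtof(standard_props(), inst, signal_counts = 1e3, seed = 22)
  expect_error(fit_optical_properties(d, irf), "floor")

  d2 <- synthesize_dtof(standard_props(), inst, signal_counts = 1e6, seed = 23)
  bad_irf <- irf
  bad_irf$channel_width_ps <- 7
  expect_error(fit_optical_properties(d2, bad_irf), "channel width")

  fit <- fit_optical_properties(d2, irf)
  expect_s3_class(fit, "dtof_fit")
  expect_named(coef(fit), c("mua", "musp", "amplitude", "t0_shift_ps"))
  expect_length(predict(fit), length(d2$counts))
  expect_lt(abs(mean(residuals(fit))), 0.5)   # Pearson residuals centred
  expect_lt(fit$reduced_chi2, 2)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "dtof")
  expect_output(print(fit), "mua")
  expect_output(print(summary(fit)), "residuals")
})

test_that("retrieval precision follows the N^(-1/2) counting-noise law", {
  # desk-scale version over two decades; the full four-decade check lives
  # with the acceptance suite
  inst <- typical_instrument()
  irf <- make_irf(inst, seed = 30)
  levels <- c(1e4, 1e6)
  cvs <- vapply(seq_along(levels), function(j) {
    est <- vapply(1:8, function(i) {
      d <- synthesize_dtof(optical_props(0.05, 10), inst,
                           signal_counts = levels[j], seed = 300 + 10 * j + i)
      coef(fit_optical_properties(d, irf, floor_counts = 1e3))[["mua"]]
    }, numeric(1))
    cv(est)
  }, numeric(1))
  slope <- (log10(cvs[2]) - log10(cvs[1])) / 2
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.7)
})
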