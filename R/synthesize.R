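# Synthetic-data generation: virtual phantom kits and virtual measurements.
# Defaults reproduce the standard acquisition conditions of the protocols:
# 1-s acquisitions, 20 repetitions, 5e5 counts/s target rate.

#' The virtual 32-phantom optical-properties kit
#'
#' The full grid of homogeneous solid phantoms used for the accuracy,
#' linearity and crosstalk tests: nominal absorption from 0 to 0.35 cm^-1 in
#' steps of 0.05 cm^-1 (digits 1--8) crossed with nominal reduced scattering
#' from 5 to 20 cm^-1 in steps of 5 cm^-1 (letters A--D), at 800 nm. The
#' letter/digit labelling is anchored at B2 = (0.05, 10) cm^-1 and
#' B3 = (0.1, 10) cm^-1.
#'
#' @return A data frame with columns `label`, `mua`, `musp`,
#'   `wavelength_nm`, one row per phantom (32 rows).
#' @examples
#' kit <- medphot_kit()
#' subset(kit, label %in% c("B2", "B3"))
#' @export
medphot_kit <- function() {
  letters_ <- c("A", "B", "C", "D")
  musp <- c(5, 10, 15, 20)
  mua <- seq(0, 0.35, by = 0.05)
  grid <- expand.grid(digit = 1:8, letter = 1:4)
  data.frame(label = paste0(letters_[grid$letter], grid$digit),
             mua = mua[grid$digit], musp = musp[grid$letter],
             wavelength_nm = 800, stringsAsFactors = FALSE)
}

# Per-channel expectation of a homogeneous measurement: forward model
# convolved with the IRF shape, scaled to `signal_counts` in-grid, plus
# uniform dark expectation, all modulated by the DNL pattern. Returns the
# expectation vector with the signal scale factor attached.
.dtof_expectation <- function(props, geom, instrument, signal_counts,
                              acquisition_time_s = 1,
                              forward = NULL, amp_factor = 1,
                              irf_override = NULL) {
  n <- instrument$n_channels
  dt <- instrument$channel_width_ps
  tc <- (seq_len(n) - 0.5) * dt
  if (is.null(forward)) {
    forward <- if (geom$mode == "reflectance")
      td_reflectance(geom$rho_mm, tc, props, geom)
    else
      td_transmittance(tc, props, geom)
  }
  irf <- if (is.null(irf_override)) instrument$irf else irf_override
  s <- .irf_shape(irf, instrument)
  conv <- .conv_open(forward, s)
  scale <- signal_counts * amp_factor / sum(conv)
  sig <- conv * scale
  dark <- instrument$dark_rate_cps * acquisition_time_s / n
  mu <- (sig + dark) * instrument$dnl_pattern
  attr(mu, "signal_scale") <- scale
  mu
}

# discrete linear convolution, first n samples
.conv_open <- function(f, s) {
  n <- length(f)
  z <- stats::convolve(f, rev(s), type = "open")
  pmax(z[seq_len(n)], 0)
}

#' Synthesize one homogeneous DTOF measurement
#'
#' Expectation = (diffusion forward model convolved with the IRF) scaled to
#' `signal_counts` within the channel grid, plus a uniform dark-count
#' expectation, each channel modulated by the instrument's DNL pattern, then
#' Poisson-sampled. A fixed seed gives bit-identical output.
#'
#' @param props [optical_props()].
#' @param instrument [instrument_model()].
#' @param geom [geometry()].
#' @param signal_counts Target total signal counts; the default 5e5 is the
#'   standard 1-s acquisition at the 5e5 s^-1 target count rate.
#' @param acquisition_time_s Acquisition time, s (drives the dark
#'   expectation).
#' @param wavelength_nm Wavelength tag, nm.
#' @param seed Optional integer seed.
#' @param sample Poisson-sample the expectation? `FALSE` returns the rounded
#'   expectation curve (a "noise-free" histogram).
#'
#' @return A [dtof()] of kind `"measurement"` with the expectation attached.
#' @export
synthesize_dtof <- function(props, instrument, geom = geometry(),
                            signal_counts = 5e5, acquisition_time_s = 1,
                            wavelength_nm = 830, seed = NULL, sample = TRUE) {
  stopifnot(inherits(props, "optical_props"),
            inherits(instrument, "instrument_model"), signal_counts > 0)
  mu <- .dtof_expectation(props, geom, instrument, signal_counts,
                          acquisition_time_s)
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("internal error: non-finite or negative channel expectation")
  counts <- if (sample) .with_seed(seed, stats::rpois(length(mu), mu)) else round(mu)
  dtof(counts, instrument$channel_width_ps,
       t0_channel = which.max(.irf_shape(instrument$irf, instrument)),
       acquisition_time_s = acquisition_time_s,
       wavelength_nm = wavelength_nm, geom = geom,
       kind = "measurement", expectation = as.numeric(mu))
}

#' Synthesize a long stability measurement series
#'
#' Repeated acquisitions over at least an hour with the instrument's slow
#' drift applied linearly in elapsed time: fractional amplitude drift
#' `drift_amp_per_min` and IRF-timing drift `drift_t0_ps_per_min`.
#'
#' @inheritParams synthesize_dtof
#' @param duration_min Total duration, minutes; below 60 a protocol-deviation
#'   warning is raised.
#' @param period_s Time between acquisitions, s.
#'
#' @return List with `time_min` (acquisition epochs) and `dtofs` (list of
#'   [dtof()]), class `"stability_series"`.
#' @export
synthesize_stability_series <- function(props, instrument,
                                        geom = geometry(),
                                        duration_min = 60, period_s = 300,
                                        signal_counts = 5e5, seed = NULL) {
  if (duration_min < 60)
    warning("stability series shorter than 60 min: protocol deviation",
            call. = FALSE)
  times_min <- seq(0, duration_min, by = period_s / 60)
  .with_seed(seed, {
    dtofs <- lapply(times_min, function(tm) {
      irf_t <- instrument$irf
      irf_t$t0_ps <- irf_t$t0_ps + instrument$drift_t0_ps_per_min * tm
      amp <- 1 + instrument$drift_amp_per_min * tm
      mu <- .dtof_expectation(props, geom, instrument, signal_counts,
                              amp_factor = amp, irf_override = irf_t)
      dtof(stats::rpois(length(mu), mu), instrument$channel_width_ps,
           t0_channel = which.max(.irf_shape(instrument$irf, instrument)),
           geom = geom, kind = "measurement", expectation = as.numeric(mu))
    })
    structure(list(time_min = times_min, dtofs = dtofs),
              class = "stability_series")
  })
}

#' Synthesize repeated acquisitions at several count levels
#'
#' The noise-test fixture: `n_reps` independent 1-s acquisitions at each
#' total-count level.
#'
#' @inheritParams synthesize_dtof
#' @param count_levels Vector of target total signal counts.
#' @param n_reps Repetitions per level (default 20).
#'
#' @return List with `count_levels` and `dtofs` (list over levels of lists of
#'   [dtof()]), class `"noise_series"`.
#' @export
synthesize_noise_series <- function(props, instrument, geom = geometry(),
                                    count_levels = c(1e4, 1e5, 1e6),
                                    n_reps = 20, seed = NULL) {
  stopifnot(all(count_levels > 0), n_reps >= 2)
  .with_seed(seed, {
    dtofs <- lapply(count_levels, function(N) {
      mu <- .dtof_expectation(props, geom, instrument, N)
      lapply(seq_len(n_reps), function(i) {
        dtof(stats::rpois(length(mu), mu), instrument$channel_width_ps,
             t0_channel = which.max(.irf_shape(instrument$irf, instrument)),
             geom = geom, kind = "measurement", expectation = as.numeric(mu))
      })
    })
    structure(list(count_levels = count_levels, n_reps = n_reps,
                   dtofs = dtofs), class = "noise_series")
  })
}

#' Synthesize multi-session (day-to-day) measurements
#'
#' Each session perturbs the instrument state by its `session_jitter`:
#' amplitude, IRF width and IRF timing each receive an independent Gaussian
#' fractional perturbation of that magnitude (timing as a fraction of the IRF
#' FWHM). Analysis of the sessions with the instrument's *nominal* IRF then
#' exhibits day-to-day reproducibility error, as in practice where the IRF is
#' calibrated once.
#'
#' @inheritParams synthesize_dtof
#' @param n_sessions Number of sessions (default 3).
#' @param n_reps Repetitions per session.
#'
#' @return List with `sessions` (list over sessions of lists of [dtof()]),
#'   class `"session_series"`.
#' @export
synthesize_sessions <- function(props, instrument, geom = geometry(),
                                n_sessions = 3, n_reps = 20,
                                signal_counts = 5e5, seed = NULL) {
  stopifnot(n_sessions >= 2)
  .with_seed(seed, {
    sessions <- lapply(seq_len(n_sessions), function(s) {
      j <- instrument$session_jitter
      irf_s <- instrument$irf
      amp <- 1
      if (j > 0) {
        amp <- max(0.1, 1 + stats::rnorm(1, 0, j))
        irf_s$fwhm_ps <- irf_s$fwhm_ps * max(0.2, 1 + stats::rnorm(1, 0, j))
        irf_s$t0_ps <- irf_s$t0_ps + stats::rnorm(1, 0, j * irf_s$fwhm_ps)
      }
      mu <- .dtof_expectation(props, geom, instrument, signal_counts,
                              amp_factor = amp, irf_override = irf_s)
      lapply(seq_len(n_reps), function(i) {
        dtof(stats::rpois(length(mu), mu), instrument$channel_width_ps,
             t0_channel = which.max(.irf_shape(instrument$irf, instrument)),
             geom = geom, kind = "measurement", expectation = as.numeric(mu))
      })
    })
    structure(list(sessions = sessions, n_sessions = n_sessions),
              class = "session_series")
  })
}

#' Synthesize a DNL (flat-light) measurement
#'
#' The differential-nonlinearity fixture: a temporally constant light source
#' recorded until each channel holds at least `counts_per_channel` counts in
#' expectation. The expectation is exactly proportional to the instrument's
#' DNL pattern.
#'
#' @param instrument [instrument_model()].
#' @param counts_per_channel Mean counts per channel (>= 1e5 recommended).
#' @param seed Optional integer seed.
#' @param sample Poisson-sample? Default `TRUE`.
#'
#' @return A [dtof()] of kind `"dnl"`.
#' @export
synthesize_dnl_measurement <- function(instrument, counts_per_channel = 1e5,
                                       seed = NULL, sample = TRUE) {
  stopifnot(counts_per_channel > 0)
  mu <- counts_per_channel * instrument$dnl_pattern
  counts <- if (sample) .with_seed(seed, stats::rpois(length(mu), mu)) else round(mu)
  dtof(counts, instrument$channel_width_ps, kind = "dnl",
       expectation = as.numeric(mu))
}

#' Synthesize a dark measurement
#'
#' Laser off: uniform dark-count expectation
#' `dark_rate_cps * tmeas_s / n_channels` per channel, Poisson-sampled.
#'
#' @param instrument [instrument_model()].
#' @param tmeas_s Measurement time, s.
#' @param seed Optional integer seed.
#'
#' @return A [dtof()] of kind `"dark"`.
#' @export
synthesize_dark <- function(instrument, tmeas_s = 1, seed = NULL) {
  stopifnot(tmeas_s > 0)
  mu <- rep(instrument$dark_rate_cps * tmeas_s / instrument$n_channels,
            instrument$n_channels)
  counts <- .with_seed(seed, stats::rpois(length(mu), mu))
  dtof(counts, instrument$channel_width_ps, acquisition_time_s = tmeas_s,
       kind = "dark", expectation = as.numeric(mu))
}

#' Synthesize a depth scan over an absorbing inclusion
#'
#' The inhomogeneity-detection fixture: repeated reflectance acquisitions
#' with the inclusion at each depth, plus repeated acquisitions of the
#' homogeneous baseline. The perturbed expectations share the baseline's
#' amplitude calibration, so contrast reflects only the inclusion.
#'
#' @inheritParams synthesize_dtof
#' @param depths_mm Inclusion depths to scan, mm.
#' @param incl [inclusion_spec()]; its `depth_mm` is overridden per scan
#'   position. Default is the standard perturbation (0.17 cm^-1 x 1 cm^3).
#' @param background Background [optical_props()]; default the standard
#'   (0.1, 10) cm^-1 phantom.
#' @param n_reps Repetitions per position and for the baseline (default 20).
#'
#' @return An object of class `"depth_scan"`: list with `depths_mm`, `dtofs`
#'   (per-depth list of [dtof()] lists), `baseline` (list of [dtof()]),
#'   `n_reps`, `t0_channel`.
#' @export
synthesize_depth_scan <- function(instrument, depths_mm = seq(2, 30, by = 2),
                                  incl = inclusion_spec(10),
                                  background = optical_props(0.1, 10),
                                  geom = geometry(), n_reps = 20,
                                  signal_counts = 5e5, seed = NULL) {
  stopifnot(n_reps >= 2, length(depths_mm) >= 1)
  n <- instrument$n_channels
  dt <- instrument$channel_width_ps
  tc <- (seq_len(n) - 0.5) * dt
  mu0 <- .dtof_expectation(background, geom, instrument, signal_counts)
  scale <- attr(mu0, "signal_scale")
  dark <- instrument$dark_rate_cps / n
  s <- .irf_shape(instrument$irf, instrument)
  t0_channel <- which.max(s)
  .with_seed(seed, {
    baseline <- lapply(seq_len(n_reps), function(i) {
      dtof(stats::rpois(n, mu0), dt, t0_channel = t0_channel, geom = geom,
           kind = "measurement", expectation = as.numeric(mu0))
    })
    dtofs <- lapply(depths_mm, function(d) {
      inc_d <- incl
      inc_d$depth_mm <- d
      fwd <- suppressWarnings(
        td_perturbed_reflectance(geom$rho_mm, tc, background, inc_d, geom,
                                 dt_quad_ps = min(dt, 25) / 4))
      mu <- (.conv_open(fwd, s) * scale + dark) * instrument$dnl_pattern
      lapply(seq_len(n_reps), function(i) {
        dtof(stats::rpois(n, mu), dt, t0_channel = t0_channel, geom = geom,
             kind = "measurement", expectation = as.numeric(mu))
      })
    })
    structure(list(depths_mm = depths_mm, dtofs = dtofs, baseline = baseline,
                   n_reps = n_reps, t0_channel = t0_channel,
                   channel_width_ps = dt),
              class = "depth_scan")
  })
}

#' Synthesize a responsivity measurement
#'
#' Round-trip fixture for the responsivity formula: given a true detection
#' responsivity (m^2 sr), the expected background-subtracted total count is
#' `true_responsivity * tmeas_s * kappa_p * Pin_W`, Poisson-sampled.
#'
#' @param instrument [instrument_model()].
#' @param kappa_p Phantom photon transmittance factor, W^-1 s^-1 m^-2 sr^-1.
#' @param Pin_W Input power, W (> 0).
#' @param tmeas_s Measurement time, s.
#' @param true_responsivity True detection responsivity, m^2 sr.
#' @param seed Optional integer seed.
#'
#' @return A [responsivity_inputs()] record.
#' @export
synthesize_responsivity_measurement <- function(instrument, kappa_p, Pin_W,
                                                tmeas_s, true_responsivity,
                                                seed = NULL) {
  if (Pin_W <= 0) stop("'Pin_W' must be > 0")
  stopifnot(kappa_p > 0, tmeas_s > 0, true_responsivity >= 0)
  lambda <- true_responsivity * tmeas_s * kappa_p * Pin_W
  Ntot <- .with_seed(seed, stats::rpois(1, lambda))
  responsivity_inputs(Ntot = Ntot, tmeas_s = tmeas_s, kappa_p = kappa_p,
                      Pin_W = Pin_W)
}
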