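# Virtual TCSPC instrument: IRF model, instrument description, and the DTOF
# (distribution of times of flight) record that every protocol test consumes.

#' Parametric instrument-response-function model
#'
#' Gaussian core plus an optional exponential tail, as an area-weighted
#' mixture. The tail emulates the slow diffusion tail of silicon-based
#' single-photon detectors; hybrid-PMT-like responses are obtained with
#' `tail_fraction = 0`.
#'
#' @param fwhm_ps Full width at half maximum of the Gaussian core, ps. The
#'   default 230 ps is a typical single-photon timing response for the
#'   instrument class being emulated.
#' @param tail_fraction Fraction of total IRF area in the exponential tail,
#'   in `[0, 1)`.
#' @param tail_tau_ps Decay constant of the tail, ps.
#' @param t0_ps Position of the IRF peak on the acquisition time axis, ps.
#'
#' @return An object of class `"irf_model"`.
#' @export
irf_model <- function(fwhm_ps = 230, tail_fraction = 0,
                      tail_tau_ps = 500, t0_ps = 1000) {
  stopifnot(fwhm_ps > 0, tail_fraction >= 0, tail_fraction < 1, tail_tau_ps > 0)
  structure(list(fwhm_ps = fwhm_ps, tail_fraction = tail_fraction,
                 tail_tau_ps = tail_tau_ps, t0_ps = t0_ps),
            class = "irf_model")
}

#' Virtual time-domain instrument
#'
#' Describes the virtual instrument driving the synthetic-data generator: the
#' IRF, the TCSPC channel grid, dark counts, differential nonlinearity (DNL,
#' a static multiplicative modulation of channel widths), slow drift, and
#' session-to-session variability. Defect terms default to zero so that an
#' `instrument_model()` out of the box is a clean, stable instrument; each
#' defect is injected explicitly by the test that probes it.
#'
#' @param irf [irf_model()].
#' @param channel_width_ps TCSPC channel width, ps.
#' @param n_channels Number of time channels (>= 16).
#' @param dark_rate_cps Dark count rate, counts/s, spread uniformly over
#'   channels.
#' @param dnl_pattern Per-channel relative channel-width multipliers with
#'   mean 1 (length `n_channels`, or length 1 recycled). `NULL` means a flat
#'   (ideal) pattern.
#' @param drift_amp_per_min Fractional amplitude drift per minute.
#' @param drift_t0_ps_per_min Timing (IRF peak) drift, ps per minute.
#' @param session_jitter Fractional day-to-day perturbation applied to
#'   amplitude, IRF width and timing between measurement sessions.
#'
#' @return An object of class `"instrument_model"`.
#' @export
instrument_model <- function(irf = irf_model(), channel_width_ps = 10,
                             n_channels = 1024, dark_rate_cps = 1000,
                             dnl_pattern = NULL, drift_amp_per_min = 0,
                             drift_t0_ps_per_min = 0, session_jitter = 0) {
  stopifnot(inherits(irf, "irf_model"), channel_width_ps > 0,
            n_channels >= 16, dark_rate_cps >= 0, session_jitter >= 0)
  if (is.null(dnl_pattern)) dnl_pattern <- rep(1, n_channels)
  if (length(dnl_pattern) == 1L) dnl_pattern <- rep(dnl_pattern, n_channels)
  if (length(dnl_pattern) != n_channels)
    stop("'dnl_pattern' must have length 1 or n_channels")
  if (any(dnl_pattern <= 0)) stop("'dnl_pattern' entries must be > 0")
  if (abs(mean(dnl_pattern) - 1) > 1e-9)
    stop("'dnl_pattern' must have mean 1 (got ", format(mean(dnl_pattern)), ")")
  structure(list(irf = irf, channel_width_ps = channel_width_ps,
                 n_channels = as.integer(n_channels),
                 dark_rate_cps = dark_rate_cps, dnl_pattern = dnl_pattern,
                 drift_amp_per_min = drift_amp_per_min,
                 drift_t0_ps_per_min = drift_t0_ps_per_min,
                 session_jitter = session_jitter),
            class = "instrument_model")
}

#' Photon time-of-flight histogram (DTOF)
#'
#' The universal measurement record: non-negative integer photon counts per
#' TCSPC time channel plus acquisition metadata. Channel `k` spans times
#' `[(k-1), k) * channel_width_ps`; expectation curves produced by the
#' generator are carried alongside the sampled counts for oracle checks.
#'
#' @param counts Non-negative integer counts per channel.
#' @param channel_width_ps Channel width, ps.
#' @param t0_channel Index of the nominal time origin channel.
#' @param acquisition_time_s Acquisition time, s.
#' @param wavelength_nm Wavelength, nm.
#' @param geom [geometry()] or `NULL`.
#' @param kind One of `"measurement"`, `"irf"`, `"dark"`, `"dnl"`.
#' @param expectation Optional per-channel expectation curve (same length).
#'
#' @return An object of class `"dtof"`.
#' @export
dtof <- function(counts, channel_width_ps, t0_channel = 1L,
                 acquisition_time_s = 1, wavelength_nm = 830,
                 geom = NULL, kind = c("measurement", "irf", "dark", "dnl"),
                 expectation = NULL) {
  kind <- match.arg(kind)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  stopifnot(channel_width_ps > 0, acquisition_time_s > 0)
  if (!is.null(expectation) && length(expectation) != length(counts))
    stop("'expectation' must match 'counts' in length")
  structure(list(counts = as.numeric(round(counts)),
                 channel_width_ps = channel_width_ps,
                 t0_channel = as.integer(t0_channel),
                 acquisition_time_s = acquisition_time_s,
                 wavelength_nm = wavelength_nm, geom = geom, kind = kind,
                 expectation = expectation),
            class = "dtof")
}

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf("DTOF [%s]: %d channels x %.3g ps, %.3g s acquisition, %g nm\n",
              x$kind, length(x$counts), x$channel_width_ps,
              x$acquisition_time_s, x$wavelength_nm))
  cat(sprintf("  total counts: %.0f, peak channel: %d\n",
              sum(x$counts), which.max(x$counts)))
  invisible(x)
}

#' @export
plot.dtof <- function(x, log = "y", ...) {
  t <- (seq_along(x$counts) - 0.5) * x$channel_width_ps
  y <- x$counts
  if (grepl("y", log)) y <- pmax(y, 0.5)
  graphics::plot(t, y, type = "s", log = log, xlab = "time (ps)",
                 ylab = "counts", ...)
  invisible(x)
}

#' Channel-centre time axis of a DTOF, in ps
#' @param x A [dtof()].
#' @return Numeric vector of channel-centre times.
#' @export
dtof_times <- function(x) {
  stopifnot(inherits(x, "dtof"))
  (seq_along(x$counts) - 0.5) * x$channel_width_ps
}

# Evaluate the IRF shape (unit area) on an instrument's channel grid.
# Sub-channel-wide IRFs (fwhm <= channel width, no tail) collapse to a
# single channel, giving an exact delta response for oracle work.
.irf_shape <- function(irf, instrument) {
  dt <- instrument$channel_width_ps
  n <- instrument$n_channels
  if (irf$fwhm_ps < dt / 2)
    stop("IRF FWHM below half the channel width: unresolvable on this grid")
  tc <- (seq_len(n) - 0.5) * dt
  if (irf$tail_fraction == 0 && irf$fwhm_ps <= dt) {
    s <- numeric(n)
    k <- max(1L, min(n, as.integer(round(irf$t0_ps / dt + 0.5))))
    s[k] <- 1
    return(s)
  }
  sigma <- irf$fwhm_ps / (2 * sqrt(2 * log(2)))
  core <- stats::dnorm(tc, mean = irf$t0_ps, sd = sigma)
  s <- (1 - irf$tail_fraction) * core
  if (irf$tail_fraction > 0) {
    tail <- ifelse(tc >= irf$t0_ps,
                   exp(-(tc - irf$t0_ps) / irf$tail_tau_ps) / irf$tail_tau_ps,
                   0)
    s <- s + irf$tail_fraction * tail
  }
  # grid must hold essentially all of the IRF area
  span_ok <- irf$t0_ps - 4 * sigma > 0 &&
    irf$t0_ps + max(4 * sigma,
                    if (irf$tail_fraction > 0) 8 * irf$tail_tau_ps else 0) < n * dt
  if (!span_ok)
    stop("channel grid does not contain >= 99.9% of the IRF area")
  s / sum(s)
}

#' Synthesize an IRF measurement
#'
#' Evaluates the instrument's IRF model on its channel grid as a
#' deterministic expectation curve scaled to `total_counts`, optionally
#' Poisson-sampled.
#'
#' @param instrument [instrument_model()].
#' @param total_counts Target total counts in the histogram.
#' @param sample Poisson-sample the expectation? Default `TRUE`.
#' @param seed Optional integer seed (sampling is then reproducible).
#'
#' @return A [dtof()] of kind `"irf"` with the expectation curve attached.
#' @export
make_irf <- function(instrument, total_counts = 1e6, sample = TRUE,
                     seed = NULL) {
  stopifnot(inherits(instrument, "instrument_model"), total_counts > 0)
  mu <- .irf_shape(instrument$irf, instrument) * total_counts
  counts <- if (sample) .with_seed(seed, stats::rpois(length(mu), mu)) else round(mu)
  dtof(counts, instrument$channel_width_ps,
       t0_channel = which.max(mu), acquisition_time_s = 1,
       kind = "irf", expectation = mu)
}

# Run code under a temporary RNG state seeded with `seed`; NULL seed uses
# (and advances) the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
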