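# Basic instrument performance (BIP) figures of merit: IRF width,
# responsivity, differential nonlinearity, dark count rate.

#' Full width at half maximum of an IRF histogram
#'
#' Background (the median of the lowest decile of channel values) is
#' subtracted, the histogram is normalized to its peak, and the two
#' half-maximum crossings are located by linear interpolation between
#' adjacent channel centres.
#'
#' @param irf A [dtof()] holding the IRF measurement.
#' @return Width between the half-maximum crossings, ps.
#' @examples
#' inst <- instrument_model(irf = irf_model(fwhm_ps = 200), dark_rate_cps = 0)
#' irf_fwhm(make_irf(inst, sample = FALSE))
#' @export
irf_fwhm <- function(irf) {
  stopifnot(inherits(irf, "dtof"))
  y <- irf$counts
  n <- length(y)
  k <- max(1L, floor(n / 10))
  bg <- stats::median(sort(y)[seq_len(k)])
  y <- y - bg
  peak_ch <- which.max(y)
  peak <- y[peak_ch]
  if (peak <= 0) stop("IRF has no peak above background")
  half <- peak / 2
  tc <- (seq_len(n) - 0.5) * irf$channel_width_ps
  # left crossing
  below_l <- which(y[seq_len(peak_ch)] < half)
  if (!length(below_l))
    stop("half maximum not crossed on the rising flank (truncated IRF)")
  i <- below_l[length(below_l)]
  tl <- tc[i] + (half - y[i]) / (y[i + 1] - y[i]) * irf$channel_width_ps
  # right crossing
  below_r <- which(y[peak_ch:n] < half)
  if (!length(below_r))
    stop("half maximum not crossed on the falling flank (truncated IRF)")
  j <- peak_ch + below_r[1] - 1L
  tr <- tc[j - 1] + (half - y[j - 1]) / (y[j] - y[j - 1]) * irf$channel_width_ps
  tr - tl
}

#' Responsivity-measurement inputs
#'
#' The scalar inputs of the detection-responsivity formula: total
#' background-subtracted counts `Ntot` over measurement time `tmeas_s`, the
#' phantom-specific photon transmittance factor `kappa_p`
#' (W^-1 s^-1 m^-2 sr^-1) and the input power `Pin_W` (W).
#'
#' @param Ntot Background-subtracted total counts (>= 0).
#' @param tmeas_s Measurement time, s (> 0).
#' @param kappa_p Phantom photon transmittance factor (> 0).
#' @param Pin_W Input power, W (> 0).
#' @return An object of class `"responsivity_inputs"`.
#' @export
responsivity_inputs <- function(Ntot, tmeas_s, kappa_p, Pin_W) {
  if (tmeas_s <= 0 || kappa_p <= 0 || Pin_W <= 0)
    stop("'tmeas_s', 'kappa_p' and 'Pin_W' must all be > 0")
  if (Ntot < 0) stop("'Ntot' must be >= 0")
  structure(list(Ntot = Ntot, tmeas_s = tmeas_s, kappa_p = kappa_p,
                 Pin_W = Pin_W), class = "responsivity_inputs")
}

#' Detection responsivity
#'
#' `Ntot / (tmeas * kappa_p * Pin)`: the ratio of photons counted by the
#' instrument to the photon radiance exiting the diffusive responsivity
#' phantom, in m^2 sr.
#'
#' @param inp A [responsivity_inputs()] record.
#' @return Responsivity, m^2 sr.
#' @examples
#' responsivity(responsivity_inputs(1e6, 1, 1e8, 1e-4))  # 100 m^2 sr
#' @export
responsivity <- function(inp) {
  stopifnot(inherits(inp, "responsivity_inputs"))
  inp$Ntot / (inp$tmeas_s * inp$kappa_p * inp$Pin_W)
}

#' Differential nonlinearity of the timing electronics
#'
#' Peak-to-peak deviation of a flat-light histogram, normalized to its mean:
#' `(max - min) / mean` over the active channels. Edge channels (first and
#' last `edge_frac` of the record) are excluded.
#'
#' @param hist A [dtof()] recorded under temporally constant illumination.
#' @param edge_frac Fraction of channels excluded at each edge (default
#'   0.02).
#' @return Dimensionless DNL fraction.
#' @examples
#' d <- dtof(c(90, 100, 110), channel_width_ps = 10, kind = "dnl")
#' dnl_eps(d, edge_frac = 0)  # 0.2
#' @export
dnl_eps <- function(hist, edge_frac = 0.02) {
  stopifnot(inherits(hist, "dtof"), edge_frac >= 0, edge_frac < 0.5)
  y <- hist$counts
  n <- length(y)
  drop <- floor(n * edge_frac)
  act <- y[(1 + drop):(n - drop)]
  m <- mean(act)
  if (m == 0) stop("mean of active channels is 0")
  (max(act) - min(act)) / m
}

#' Dark count rate
#'
#' Total counts of a dark measurement (laser off) divided by its acquisition
#' time.
#'
#' @param dark A [dtof()] of kind `"dark"`.
#' @return Dark count rate, counts/s.
#' @export
dark_count_rate <- function(dark) {
  stopifnot(inherits(dark, "dtof"))
  if (dark$kind != "dark")
    stop("'dark' must be a dtof of kind \"dark\"")
  if (dark$acquisition_time_s <= 0) stop("acquisition time must be > 0")
  sum(dark$counts) / dark$acquisition_time_s
}
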