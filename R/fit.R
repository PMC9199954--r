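# Retrieval of homogeneous optical properties from a DTOF by fitting the
# IRF-convolved diffusion model with a Poisson-deviance objective.

#' Subtract background counts from a DTOF
#'
#' Removes the flat background (dark counts, ambient light) either from the
#' pre-peak region of the histogram or from a paired dark measurement.
#' Negative channels after subtraction are clipped at 0.
#'
#' @param x A [dtof()].
#' @param strategy `"prepeak"` (mean of the channels well before the rising
#'   edge) or `"dark"` (expectation of a paired dark measurement, scaled to
#'   the acquisition time).
#' @param dark A [dtof()] of kind `"dark"`, required for the `"dark"`
#'   strategy.
#' @param margin_channels Channels left between the pre-peak window and the
#'   rising edge.
#'
#' @return The background-subtracted [dtof()], with the estimated per-channel
#'   background in attribute `"background"`.
#' @export
subtract_background <- function(x, strategy = c("prepeak", "dark"),
                                dark = NULL, margin_channels = 10L) {
  stopifnot(inherits(x, "dtof"))
  strategy <- match.arg(strategy)
  if (strategy == "prepeak") {
    peak <- max(x$counts)
    rise <- which(x$counts > 0.01 * peak)[1]
    last <- rise - margin_channels - 1L
    if (is.na(last) || last < 3L)
      stop("pre-peak window overlaps the pulse: too few channels before the rising edge")
    bg <- mean(x$counts[seq_len(last)])
  } else {
    if (is.null(dark) || !inherits(dark, "dtof") || dark$kind != "dark")
      stop("'dark' must be a dtof of kind \"dark\"")
    if (length(dark$counts) != length(x$counts))
      stop("dark measurement has a different number of channels")
    bg <- mean(dark$counts) * x$acquisition_time_s / dark$acquisition_time_s
  }
  out <- x
  out$counts <- pmax(x$counts - bg, 0)
  out$expectation <- NULL
  attr(out, "background") <- bg
  out
}

# Default fit range: from the channel where the rising edge reaches 80% of
# the peak down to 1% of the peak on the tail.
.default_fit_range <- function(counts, rise_frac = 0.8, tail_frac = 0.01) {
  peak_ch <- which.max(counts)
  peak <- counts[peak_ch]
  lo <- which(counts[seq_len(peak_ch)] >= rise_frac * peak)[1]
  hi_rel <- which(counts[peak_ch:length(counts)] >= tail_frac * peak)
  hi <- peak_ch + hi_rel[length(hi_rel)] - 1L
  c(lo, hi)
}

#' Fit homogeneous optical properties to a DTOF
#'
#' Estimates the absorption and reduced scattering coefficients of a
#' homogeneous medium from a measured DTOF by minimizing the Poisson deviance
#' between the counts and `amplitude * (diffusion model convolved with the
#' measured IRF)`, over a fit range running from 80% of the peak on the
#' rising edge to 1% of the peak on the tail. Free parameters are
#' \eqn{\mu_a}, \eqn{\mu_s'}, the amplitude (profiled analytically) and,
#' by default, a timing offset `t0_shift_ps` between the IRF and the DTOF.
#'
#' The minimizer is bounded L-BFGS-B started from two initial absorption
#' guesses (0.05 and 0.2 cm^-1, both at \eqn{\mu_s'} = 10 cm^-1); bounds are
#' \eqn{\mu_a \in [0, 2]}, \eqn{\mu_s' \in [0.5, 100]} cm^-1, and an estimate
#' landing on a property bound clears the `converged` flag.
#'
#' @param x A [dtof()] measurement.
#' @param irf A [dtof()] of kind `"irf"` sharing the channel width of `x`.
#' @param geom [geometry()]; defaults to the geometry stored in `x`.
#' @param n_medium Refractive index used in the model (default 1.55).
#' @param fit_t0 Fit the timing offset? Default `TRUE`; `FALSE` pins it at 0
#'   (IRF and DTOF share their origin).
#' @param fit_range Integer channel interval `c(lo, hi)`; `NULL` selects the
#'   default range described above.
#' @param subtract_bg Subtract the pre-peak background from `x` before
#'   fitting? Default `TRUE`.
#' @param floor_counts Minimum total counts required (default 1e4).
#'
#' @return An object of class `"dtof_fit"`; see [coef.dtof_fit()],
#'   [predict.dtof_fit()], [summary.dtof_fit()].
#' @examples
#' inst <- instrument_model(dark_rate_cps = 0)
#' d <- synthesize_dtof(optical_props(0.1, 10), inst, signal_counts = 1e6,
#'                      seed = 1)
#' irf <- make_irf(inst, seed = 2)
#' fit <- fit_optical_properties(d, irf)
#' coef(fit)
#' @export
fit_optical_properties <- function(x, irf, geom = x$geom, n_medium = 1.55,
                                   fit_t0 = TRUE, fit_range = NULL,
                                   subtract_bg = TRUE, floor_counts = 1e4) {
  stopifnot(inherits(x, "dtof"), inherits(irf, "dtof"))
  if (abs(x$channel_width_ps - irf$channel_width_ps) > 1e-9)
    stop("DTOF and IRF must share the channel width")
  if (is.null(geom)) geom <- geometry()
  if (sum(x$counts) < floor_counts)
    stop("total counts below the configured floor (", floor_counts, ")")
  bg <- 0
  if (subtract_bg) {
    xs <- try(subtract_background(x, "prepeak"), silent = TRUE)
    if (!inherits(xs, "try-error")) {
      bg <- attr(xs, "background")
      x <- xs
    }
  }
  y_all <- x$counts
  if (is.null(fit_range)) fit_range <- .default_fit_range(y_all)
  fit_range <- as.integer(fit_range)
  if (fit_range[1] < 1 || fit_range[2] > length(y_all) ||
      fit_range[2] - fit_range[1] < 10)
    stop("invalid fit range")
  idx <- fit_range[1]:fit_range[2]
  y <- y_all[idx]

  n <- length(y_all)
  dt <- x$channel_width_ps
  tc <- (seq_len(n) - 0.5) * dt
  s_irf <- irf$counts / sum(irf$counts)

  shape_fun <- function(mua, musp, t0) {
    props <- optical_props(mua, musp, n_medium)
    fwd <- if (geom$mode == "reflectance")
      td_reflectance(geom$rho_mm, tc, props, geom)
    else
      td_transmittance(tc, props, geom)
    m <- .conv_open(fwd, s_irf)
    if (t0 != 0)
      m <- stats::approx(tc, m, xout = tc - t0, rule = 2)$y
    m[idx]
  }

  objective <- function(par) {
    t0 <- if (fit_t0) par[3] else 0
    s <- shape_fun(par[1], par[2], t0)
    ssum <- sum(s)
    if (!is.finite(ssum) || ssum <= 0) return(1e12)
    A <- sum(y) / ssum
    m <- pmax(A * s, 1e-12)
    2 * sum(m - y + ifelse(y > 0, y * log(y / m), 0))
  }

  lower <- c(0, 0.5, -500)[seq_len(2 + fit_t0)]
  upper <- c(2, 100, 500)[seq_len(2 + fit_t0)]
  scale <- c(0.1, 10, 50)[seq_len(2 + fit_t0)]
  starts <- list(c(0.05, 10, 0)[seq_len(2 + fit_t0)],
                 c(0.2, 10, 0)[seq_len(2 + fit_t0)])

  best <- NULL
  for (p0 in starts) {
    res <- try(stats::optim(p0, objective, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(parscale = scale, maxit = 200)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }

  if (is.null(best)) {
    par <- c(NA_real_, NA_real_, NA_real_)
    conv <- FALSE
    devv <- NA_real_
    A <- NA_real_
    shape <- NULL
  } else {
    par <- c(best$par, 0)[1:3]
    tolb <- 1e-6
    at_bound <- par[1] >= 2 - tolb || par[2] <= 0.5 + tolb || par[2] >= 100 - tolb
    conv <- best$convergence == 0 && !at_bound
    devv <- best$value
    shape <- shape_fun(par[1], par[2], if (fit_t0) par[3] else 0)
    A <- sum(y) / sum(shape)
  }

  structure(list(
    props = if (conv || !is.na(par[1])) optical_props(max(par[1], 0), par[2], n_medium) else NULL,
    amplitude = A,
    t0_shift_ps = if (fit_t0) par[3] else 0,
    deviance = devv,
    reduced_chi2 = devv / (length(y) - (2 + fit_t0)),
    fit_range = fit_range,
    converged = conv,
    background = bg,
    dtof = x, irf_shape = s_irf, geom = geom, n_medium = n_medium,
    fitted_range_curve = if (is.null(shape)) NULL else A * shape
  ), class = "dtof_fit")
}

#' @export
print.dtof_fit <- function(x, ...) {
  cat("Optical-property fit (IRF-convolved diffusion model)\n")
  if (!is.null(x$props))
    cat(sprintf("  mua  = %.5f cm^-1\n  mus' = %.4f cm^-1\n",
                x$props$mua, x$props$musp))
  cat(sprintf("  t0 shift = %.2f ps, reduced deviance = %.3f, converged: %s\n",
              x$t0_shift_ps, x$reduced_chi2, x$converged))
  cat(sprintf("  fit range: channels %d-%d\n", x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Coefficients of an optical-property fit
#' @param object A `"dtof_fit"`.
#' @param ... Unused.
#' @return Named vector `mua`, `musp` (cm^-1), `amplitude`, `t0_shift_ps`.
#' @export
coef.dtof_fit <- function(object, ...) {
  c(mua = if (is.null(object$props)) NA_real_ else object$props$mua,
    musp = if (is.null(object$props)) NA_real_ else object$props$musp,
    amplitude = object$amplitude,
    t0_shift_ps = object$t0_shift_ps)
}

#' Expected counts from a fitted model
#'
#' @param object A `"dtof_fit"`.
#' @param full Return the whole channel grid (`TRUE`) or only the fit range?
#' @param ... Unused.
#' @return Numeric vector of expected counts.
#' @export
predict.dtof_fit <- function(object, full = TRUE, ...) {
  n <- length(object$dtof$counts)
  dt <- object$dtof$channel_width_ps
  tc <- (seq_len(n) - 0.5) * dt
  props <- object$props
  fwd <- if (object$geom$mode == "reflectance")
    td_reflectance(object$geom$rho_mm, tc, props, object$geom)
  else
    td_transmittance(tc, props, object$geom)
  m <- .conv_open(fwd, object$irf_shape)
  if (object$t0_shift_ps != 0)
    m <- stats::approx(tc, m, xout = tc - object$t0_shift_ps, rule = 2)$y
  idx <- object$fit_range[1]:object$fit_range[2]
  A <- sum(object$dtof$counts[idx]) / sum(m[idx])
  out <- A * m
  if (full) out else out[idx]
}

#' @export
residuals.dtof_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  idx <- object$fit_range[1]:object$fit_range[2]
  y <- object$dtof$counts[idx]
  m <- pmax(predict(object, full = TRUE)[idx], 1e-12)
  if (type == "pearson") (y - m) / sqrt(m)
  else sign(y - m) * sqrt(2 * (m - y + ifelse(y > 0, y * log(y / m), 0)))
}

#' @export
summary.dtof_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(coef = coef(object), converged = object$converged,
                 reduced_chi2 = object$reduced_chi2,
                 fit_range = object$fit_range,
                 resid_summary = summary(r)), class = "summary.dtof_fit")
}

#' @export
print.summary.dtof_fit <- function(x, ...) {
  cat("Optical-property fit summary\n")
  print(x$coef)
  cat(sprintf("reduced deviance: %.3f over channels %d-%d; converged: %s\n",
              x$reduced_chi2, x$fit_range[1], x$fit_range[2], x$converged))
  cat("Pearson residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
plot.dtof_fit <- function(x, ...) {
  y <- x$dtof$counts
  tc <- dtof_times(x$dtof)
  m <- predict(x, full = TRUE)
  idx <- x$fit_range[1]:x$fit_range[2]
  graphics::plot(tc, pmax(y, 0.5), type = "p", pch = ".", log = "y",
                 xlab = "time (ps)", ylab = "counts", ...)
  graphics::lines(tc[idx], pmax(m[idx], 0.5), col = 2, lwd = 2)
  graphics::abline(v = tc[x$fit_range], lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate Poisson replicates from a fitted model
#' @param object A `"dtof_fit"`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of [dtof()] objects sampled from the fitted expectation.
#' @export
simulate.dtof_fit <- function(object, nsim = 1, seed = NULL, ...) {
  m <- predict(object, full = TRUE)
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    dtof(stats::rpois(length(m), m), object$dtof$channel_width_ps,
         t0_channel = object$dtof$t0_channel, geom = object$geom,
         kind = "measurement", expectation = m)
  }))
}

#' @export
logLik.dtof_fit <- function(object, ...) {
  idx <- object$fit_range[1]:object$fit_range[2]
  y <- object$dtof$counts[idx]
  m <- pmax(predict(object, full = TRUE)[idx], 1e-12)
  ll <- sum(stats::dpois(round(y), m, log = TRUE))
  structure(ll, df = 3 + (object$t0_shift_ps != 0), class = "logLik")
}
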