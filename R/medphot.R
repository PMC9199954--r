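# Optical-property protocol figures of merit over virtual-kit measurements:
# accuracy, linearity, crosstalk, stability, noise, reproducibility.
#
# A "kit measurement" is a data frame with one row per phantom and columns
# `label`, `nominal_mua`, `nominal_musp` (the kit's design values) and
# `mua`, `musp` (retrieved estimates, typically means over repetitions).

.ols_slope <- function(x, y) {
  f <- stats::lm.fit(cbind(1, x), y)
  unname(f$coefficients[2])
}

#' Accuracy as deviation around the population median
#'
#' For one optical property measured on the same phantom by several
#' instruments, the per-instrument relative deviation from the population
#' median, `|x - median| / median * 100`, and their median as the summary
#' figure of merit. No "conventionally true" phantom value is involved.
#'
#' @param estimates Numeric vector of per-instrument estimates (>= 3).
#' @return List with `deviation_pct` (per instrument) and
#'   `median_deviation_pct`.
#' @examples
#' accuracy_deviation(c(0.09, 0.10, 0.11))
#' @export
accuracy_deviation <- function(estimates) {
  stopifnot(is.numeric(estimates))
  if (length(estimates) < 3) stop("need at least 3 instruments")
  med <- stats::median(estimates)
  if (med == 0) stop("population median is 0")
  dev <- abs(estimates - med) / med * 100
  list(deviation_pct = dev, median_deviation_pct = stats::median(dev))
}

# Split a kit measurement into series; check usability.
.kit_series <- function(kit, vary, fixed) {
  split(kit, kit[[fixed]])
}

.series_deviations <- function(kit, nominal, retrieved, fixed) {
  out <- list()
  for (ser in split(kit, kit[[fixed]])) {
    x <- ser[[nominal]]
    y <- ser[[retrieved]]
    if (nrow(ser) < 3 || length(unique(x)) < 2) {
      warning("degenerate series skipped (", fixed, " = ",
              ser[[fixed]][1], ")", call. = FALSE)
      next
    }
    f <- stats::lm.fit(cbind(1, x), y)
    yhat <- f$fitted.values
    out[[length(out) + 1]] <- abs(y - yhat) / abs(yhat) * 100
  }
  if (!length(out)) stop("no usable series")
  unlist(out)
}

#' Deviation from linearity over the phantom kit
#'
#' Within each constant-scattering series, retrieved absorption is regressed
#' on nominal absorption by ordinary least squares and each point's relative
#' deviation from the fitted line, `|y - yhat| / yhat * 100`, is recorded;
#' the figure of merit is the median deviation over all points and series.
#' The symmetric procedure within constant-absorption series gives the
#' reduced-scattering linearity.
#'
#' @param kit Kit-measurement data frame (see file header).
#' @return Named vector: `mua_pct`, `musp_pct`.
#' @export
linearity_fom <- function(kit) {
  stopifnot(is.data.frame(kit),
            all(c("nominal_mua", "nominal_musp", "mua", "musp") %in% names(kit)))
  c(mua_pct = stats::median(
      .series_deviations(kit, "nominal_mua", "mua", "nominal_musp")),
    musp_pct = stats::median(
      .series_deviations(kit, "nominal_musp", "musp", "nominal_mua")))
}

.series_slopes <- function(kit, nominal, retrieved, fixed) {
  slopes <- c()
  for (ser in split(kit, kit[[fixed]])) {
    x <- ser[[nominal]]
    if (nrow(ser) < 3 || length(unique(x)) < 2) {
      warning("degenerate series skipped (", fixed, " = ",
              ser[[fixed]][1], ")", call. = FALSE)
      next
    }
    slopes <- c(slopes, abs(.ols_slope(x, ser[[retrieved]])))
  }
  if (!length(slopes)) stop("no usable series")
  slopes
}

#' Crosstalk between the retrieved optical properties
#'
#' Within each series where one nominal property is varied and the other held
#' fixed, the *other* retrieved property is regressed on the varied nominal
#' value; the median absolute slope S over series measures the coupling.
#' Relative coupling coefficients re-express S at the reference properties
#' `mua0` = 0.1 cm^-1, `mus0` = 10 cm^-1, and are named by cause -> effect:
#'
#' * `F_mua_to_mus = S_mus_given_mua * mua0 / mus0` — an absorption change
#'   (cause) leaking into the retrieved scattering (effect);
#' * `F_mus_to_mua = S_mua_given_mus * mus0 / mua0` — a scattering change
#'   leaking into the retrieved absorption.
#'
#' A relative coupling F means a `d`% change in the causing property is
#' expected to alter the affected property by `F * d`% (see
#' [crosstalk_effect()]).
#'
#' @param kit Kit-measurement data frame.
#' @param mua0,mus0 Reference optical properties, cm^-1.
#' @return An object of class `"crosstalk_result"`: list with
#'   `S_mus_given_mua`, `S_mua_given_mus`, `F_mua_to_mus`, `F_mus_to_mua`,
#'   `mua0`, `mus0`.
#' @export
crosstalk_fom <- function(kit, mua0 = 0.1, mus0 = 10) {
  stopifnot(is.data.frame(kit))
  S_mus_given_mua <- stats::median(
    .series_slopes(kit, "nominal_mua", "musp", "nominal_musp"))
  S_mua_given_mus <- stats::median(
    .series_slopes(kit, "nominal_musp", "mua", "nominal_mua"))
  structure(list(S_mus_given_mua = S_mus_given_mua,
                 S_mua_given_mus = S_mua_given_mus,
                 F_mua_to_mus = S_mus_given_mua * mua0 / mus0,
                 F_mus_to_mua = S_mua_given_mus * mus0 / mua0,
                 mua0 = mua0, mus0 = mus0),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("Crosstalk (reference mua0 = %.3g, mus0 = %.3g cm^-1):\n",
              x$mua0, x$mus0))
  cat(sprintf("  F (mua -> mus') = %.4g   [S = %.4g]\n",
              x$F_mua_to_mus, x$S_mus_given_mua))
  cat(sprintf("  F (mus' -> mua) = %.4g   [S = %.4g]\n",
              x$F_mus_to_mua, x$S_mua_given_mus))
  invisible(x)
}

#' Crosstalk effect of a relative cause increment
#'
#' The relative change expected in the affected property when the causing
#' property changes by `cause_pct` percent, given relative coupling `F`:
#' `effect_pct = F * cause_pct`.
#'
#' @param F Relative coupling coefficient (dimensionless).
#' @param cause_pct Relative change of the causing property, %.
#' @return Expected relative change of the affected property, %.
#' @examples
#' crosstalk_effect(0.13, 10)  # 1.3
#' @export
crosstalk_effect <- function(F, cause_pct) {
  stopifnot(is.numeric(F), is.numeric(cause_pct))
  F * cause_pct
}

#' Stability figures of merit of a property time series
#'
#' For retrieved-property estimates over a long measurement: the range of
#' variation `(max - min) / mean * 100` and the drift, the absolute
#' ordinary-least-squares slope versus time normalized by the mean,
#' in % per minute.
#'
#' @param time_min Acquisition times, minutes.
#' @param values Property estimates at those times.
#' @return Named vector: `range_pct`, `drift_pct_per_min`.
#' @export
stability_fom <- function(time_min, values) {
  stopifnot(length(time_min) == length(values))
  if (length(values) < 10)
    warning("fewer than 10 points in the stability series", call. = FALSE)
  if (diff(range(time_min)) < 60)
    warning("stability series spans less than 60 min", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("series mean is 0")
  c(range_pct = (max(values) - min(values)) / m * 100,
    drift_pct_per_min = abs(.ols_slope(time_min, values)) / m * 100)
}

#' Projected deviation from a measured drift
#'
#' `drift_pct_per_min * minutes`: e.g. a drift of 0.03 %/min projects to a
#' maximum deviation of 3% over 100 minutes of continuous monitoring.
#'
#' @param drift_pct_per_min Drift, % per minute.
#' @param minutes Projection horizon, minutes (>= 0).
#' @return Projected deviation, %.
#' @export
drift_projection <- function(drift_pct_per_min, minutes) {
  stopifnot(minutes >= 0)
  drift_pct_per_min * minutes
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) of repeated measurements
#' over their mean, in %.
#'
#' @param values Numeric vector (>= 2 values).
#' @return CV, %.
#' @examples
#' cv(c(9, 10, 11))  # 10
#' @export
cv <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("mean is 0")
  stats::sd(values) / m * 100
}

#' Counts needed for 1% coefficient of variation
#'
#' From repeated property estimates at several total-count levels, the CV is
#' computed per level and a straight line is fitted to `log10(CV%)` versus
#' `log10(N)`; the figure of merit is the count level where the fitted line
#' crosses CV = 1%.
#'
#' @param counts Total counts per level (>= 3 levels spanning >= 1 decade).
#' @param estimates List (one numeric vector of repeated estimates per
#'   level), or a matrix with one row per level, or — via `cv_pct` — nothing.
#' @param cv_pct Optional precomputed CV per level, %; overrides `estimates`.
#' @return Counts at CV = 1%, with the fitted log--log `slope` and
#'   `intercept` and the per-level `cv_pct` as attributes.
#' @export
noise_fom <- function(counts, estimates = NULL, cv_pct = NULL) {
  stopifnot(length(counts) >= 3)
  if (log10(max(counts) / min(counts)) < 1)
    stop("count levels must span at least one decade")
  if (is.null(cv_pct)) {
    if (is.matrix(estimates)) estimates <- asplit(estimates, 1)
    stopifnot(length(estimates) == length(counts))
    cv_pct <- vapply(estimates, cv, numeric(1))
  }
  stopifnot(length(cv_pct) == length(counts))
  f <- stats::lm.fit(cbind(1, log10(counts)), log10(cv_pct))
  a <- f$coefficients[1]; b <- f$coefficients[2]
  if (b >= 0)
    stop("degenerate fit: CV does not decrease with counts")
  out <- unname(10^(-a / b))  # log10(CV) = 0 at CV = 1%
  attr(out, "slope") <- unname(b)
  attr(out, "intercept") <- unname(a)
  attr(out, "cv_pct") <- cv_pct
  out
}

#' Day-to-day reproducibility
#'
#' Coefficient of variation of the per-session mean property estimates over
#' the measurement sessions.
#'
#' @param session_means Per-session property estimates (>= 2 sessions).
#' @return CV, %.
#' @export
reproducibility_fom <- function(session_means) {
  cv(session_means)
}
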