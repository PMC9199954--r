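# Inhomogeneity-detection figures of merit: time-windowed contrast and
# contrast-to-noise ratio over a depth scan of an absorbing inclusion.

#' Time window on the photon time-of-flight axis
#'
#' Half-open interval `[t_start, t_end)` in ps relative to the chosen time
#' origin. The named presets follow the standard 400-ps windowing:
#' `"early"` = \[400, 800) ps and `"late"` = \[2000, 2400) ps.
#'
#' @param t_start_ps Window start, ps, or `"early"` / `"late"`.
#' @param t_end_ps Window end, ps (> start); ignored for named presets.
#' @return An object of class `"time_window"`.
#' @examples
#' time_window(400, 800)
#' time_window("late")
#' @export
time_window <- function(t_start_ps, t_end_ps = NULL) {
  if (is.character(t_start_ps)) {
    preset <- match.arg(t_start_ps, c("early", "late"))
    b <- if (preset == "early") c(400, 800) else c(2000, 2400)
    return(structure(list(t_start_ps = b[1], t_end_ps = b[2], name = preset),
                     class = "time_window"))
  }
  stopifnot(is.numeric(t_start_ps), is.numeric(t_end_ps))
  if (t_end_ps <= t_start_ps) stop("'t_end_ps' must exceed 't_start_ps'")
  structure(list(t_start_ps = t_start_ps, t_end_ps = t_end_ps,
                 name = sprintf("[%g,%g)", t_start_ps, t_end_ps)),
            class = "time_window")
}

#' Counts of a DTOF inside a time window
#'
#' Sums the counts in `[t_ref + t_start, t_ref + t_end)`; channels partially
#' covered at the window edges contribute in proportion to their overlap
#' (counts treated as uniform within a channel).
#'
#' @param x A [dtof()].
#' @param window A [time_window()].
#' @param t_ref_ps Time origin on the histogram axis, ps. Defaults to the
#'   centre of the DTOF's `t0_channel` (the IRF peak, for generator output).
#' @return Window counts (fractional at the edges).
#' @export
window_counts <- function(x, window, t_ref_ps = NULL) {
  stopifnot(inherits(x, "dtof"), inherits(window, "time_window"))
  dt <- x$channel_width_ps
  if (is.null(t_ref_ps)) t_ref_ps <- (x$t0_channel - 0.5) * dt
  a <- t_ref_ps + window$t_start_ps
  b <- t_ref_ps + window$t_end_ps
  n <- length(x$counts)
  if (a < 0 || b > n * dt)
    stop("window falls outside the histogram span")
  if (a == b) return(0)
  # channel k spans [(k-1) dt, k dt)
  edges_lo <- (seq_len(n) - 1) * dt
  overlap <- pmin(edges_lo + dt, b) - pmax(edges_lo, a)
  sum(x$counts * pmax(overlap, 0) / dt)
}

#' Contrast of an inclusion measurement
#'
#' Relative difference in (windowed) counts between the inclusion at
#' position i and the homogeneous baseline: `(Mi - M0) / M0`.
#'
#' @param Mi Counts with the inclusion in place.
#' @param M0 Baseline (homogeneous) counts (> 0).
#' @return Signed contrast.
#' @export
contrast <- function(Mi, M0) {
  if (any(M0 == 0)) stop("baseline counts M0 must be > 0")
  (Mi - M0) / M0
}

#' Contrast-to-noise ratio
#'
#' `(Mi - mean(M0)) / sd(M0)` where the baseline repetitions supply both the
#' reference level and the noise scale.
#'
#' @param Mi Counts with the inclusion in place.
#' @param M0_reps Baseline window counts over repeated acquisitions (>= 2).
#' @return Signed CNR.
#' @export
cnr <- function(Mi, M0_reps) {
  stopifnot(length(M0_reps) >= 2)
  s <- stats::sd(M0_reps)
  if (s == 0) stop("baseline repetitions have zero standard deviation")
  (Mi - mean(M0_reps)) / s
}

#' Depth-resolved contrast and CNR profile
#'
#' For each inclusion depth and each time window: `Mi` is the mean window
#' count over the position's repetitions, the baseline mean and standard
#' deviation come from the homogeneous repetitions, and contrast and CNR
#' follow their definitions.
#'
#' @param scan A `"depth_scan"` from [synthesize_depth_scan()] (or of the
#'   same shape).
#' @param windows List of [time_window()]s; default early + late presets.
#' @param t_ref_ps Time origin, ps; default the scan's IRF-peak channel.
#' @return An object of class `"contrast_profile"`: list with `depths_mm`,
#'   matrices `contrast` and `cnr` (depth x window), `Mi`, `M0`, `sd_M0`,
#'   window names.
#' @export
depth_profile <- function(scan, windows = list(time_window("early"),
                                               time_window("late")),
                          t_ref_ps = NULL) {
  stopifnot(inherits(scan, "depth_scan") || is.list(scan))
  if (length(scan$baseline) < 2) stop("need >= 2 baseline repetitions")
  if (is.null(t_ref_ps))
    t_ref_ps <- (scan$t0_channel - 0.5) * scan$channel_width_ps
  wnames <- vapply(windows, function(w) w$name, character(1))
  nd <- length(scan$depths_mm); nw <- length(windows)
  M0m <- numeric(nw); M0s <- numeric(nw)
  for (j in seq_len(nw)) {
    reps <- vapply(scan$baseline, window_counts, numeric(1),
                   window = windows[[j]], t_ref_ps = t_ref_ps)
    M0m[j] <- mean(reps); M0s[j] <- stats::sd(reps)
  }
  Mi <- matrix(NA_real_, nd, nw, dimnames = list(NULL, wnames))
  for (i in seq_len(nd)) for (j in seq_len(nw)) {
    reps <- vapply(scan$dtofs[[i]], window_counts, numeric(1),
                   window = windows[[j]], t_ref_ps = t_ref_ps)
    Mi[i, j] <- mean(reps)
  }
  C <- sweep(sweep(Mi, 2, M0m, "-"), 2, M0m, "/")
  if (any(M0s == 0)) stop("baseline repetitions have zero standard deviation")
  CNR <- sweep(sweep(Mi, 2, M0m, "-"), 2, M0s, "/")
  structure(list(depths_mm = scan$depths_mm, windows = wnames,
                 contrast = C, cnr = CNR, Mi = Mi, M0 = M0m, sd_M0 = M0s,
                 t_ref_ps = t_ref_ps),
            class = "contrast_profile")
}

#' @export
print.contrast_profile <- function(x, ...) {
  cat("Depth-resolved contrast profile\n")
  df <- data.frame(depth_mm = x$depths_mm)
  for (j in seq_along(x$windows)) {
    df[[paste0("C_", x$windows[j])]] <- x$contrast[, j]
    df[[paste0("CNR_", x$windows[j])]] <- x$cnr[, j]
  }
  print(df, digits = 3)
  invisible(x)
}

#' @export
plot.contrast_profile <- function(x, what = c("contrast", "cnr"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::matplot(x$depths_mm, abs(m), type = "b", pch = 1:ncol(m),
                    xlab = "inclusion depth (mm)",
                    ylab = paste0("|", what, "|"), log = "y", ...)
  graphics::legend("topright", legend = x$windows, pch = 1:ncol(m),
                   col = 1:ncol(m), lty = 1:ncol(m), bty = "n")
  invisible(x)
}

#' Depth-sensitivity figures of merit
#'
#' The magnitudes of the contrast and CNR at the chosen depth (default
#' 20 mm) and window (default the late preset). If no profiled depth lies
#' within 1 mm of the request, the nearest depth is used and recorded.
#'
#' @param profile A `"contrast_profile"`.
#' @param depth_mm Requested depth, mm.
#' @param window Window name to select (must match one of the profile's).
#' @return Named vector `contrast`, `cnr` (magnitudes), with attributes
#'   `depth_mm` (depth actually used) and `window`.
#' @export
neuropt_fom <- function(profile, depth_mm = 20, window = "late") {
  stopifnot(inherits(profile, "contrast_profile"))
  j <- match(window, profile$windows)
  if (is.na(j)) stop("window '", window, "' not in profile")
  d <- abs(profile$depths_mm - depth_mm)
  i <- which.min(d)
  if (d[i] > 1)
    warning("no profiled depth within 1 mm of ", depth_mm,
            " mm; using nearest (", profile$depths_mm[i], " mm)",
            call. = FALSE)
  out <- c(contrast = unname(abs(profile$contrast[i, j])),
           cnr = unname(abs(profile$cnr[i, j])))
  attr(out, "depth_mm") <- profile$depths_mm[i]
  attr(out, "window") <- window
  out
}

#' Continuous-wave contrast over a depth scan
#'
#' The CW instrument's view of the depth scan: contrast and CNR from the
#' *total* measured counts, i.e. [depth_profile()] with a single window
#' spanning the whole histogram.
#'
#' @param scan A `"depth_scan"`.
#' @return A `"contrast_profile"` with one window named `"total"`.
#' @export
cw_contrast <- function(scan) {
  n <- length(scan$baseline[[1]]$counts)
  dt <- scan$channel_width_ps
  w <- time_window(0, n * dt)
  w$name <- "total"
  depth_profile(scan, windows = list(w), t_ref_ps = 0)
}
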