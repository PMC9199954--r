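# Figure-of-merit bookkeeping, summary statistics, and the virtual
# measurement-campaign driver.

#' One figure-of-merit record
#'
#' The atom of the reporting layer: one synthetic indicator value with its
#' protocol, test, property tag, units and instrument identity.
#'
#' @param protocol `"BIP"`, `"MEDPHOT"` or `"NEUROPT"`.
#' @param test Test name (e.g. `"Linearity"`).
#' @param fom Figure-of-merit name.
#' @param property `"Mua"`, `"Mus"` or `"All"`.
#' @param value Finite numeric value.
#' @param units Unit string.
#' @param instrument Instrument identifier.
#' @return A one-row data frame.
#' @export
fom_record <- function(protocol, test, fom, property, value, units,
                       instrument = "virtual") {
  protocol <- match.arg(protocol, c("BIP", "MEDPHOT", "NEUROPT"))
  property <- match.arg(property, c("Mua", "Mus", "All"))
  if (!is.finite(value)) stop("FOM value must be finite")
  data.frame(protocol = protocol, test = test, fom = fom,
             property = property, value = value, units = units,
             instrument = instrument, stringsAsFactors = FALSE)
}

#' Summary statistics of figure-of-merit records
#'
#' Aggregates records per (protocol, test, fom, property): count, mean,
#' sample (n - 1) standard deviation, minimum, 25%/50%/75% percentiles by
#' linear interpolation between closest ranks, and maximum. Groups with a
#' single record report a standard deviation of 0 and are flagged in the
#' `single` column.
#'
#' @param records Data frame of [fom_record()] rows.
#' @return Data frame, one row per group, columns `protocol`, `test`, `fom`,
#'   `property`, `units`, `count`, `mean`, `std`, `min`, `p25`, `p50`,
#'   `p75`, `max`, `single`.
#' @export
summarize_foms <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  key <- interaction(records$protocol, records$test, records$fom,
                     records$property, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    v <- g$value
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(protocol = g$protocol[1], test = g$test[1], fom = g$fom[1],
               property = g$property[1], units = g$units[1],
               count = length(v), mean = mean(v),
               std = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), p25 = q[1], p50 = q[2], p75 = q[3],
               max = max(v), single = length(v) == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protocol, out$test, out$fom, out$property), ]
}

#' Configuration for a virtual measurement campaign
#'
#' Parameter ranges from which each virtual instrument is drawn (uniformly;
#' dark rate and responsivity log-uniformly), plus the problem sizes of each
#' protocol test. `ideal = TRUE` collapses every range to a clean, identical
#' instrument (narrow tail-free IRF, no dark counts, flat DNL, no drift, no
#' session jitter) — the campaign's null configuration.
#'
#' The `tests` entry selects which protocol blocks run (`"BIP"`, `"Kit"` =
#' linearity/crosstalk/accuracy, `"Stability"`, `"Noise"`,
#' `"Reproducibility"`, `"Contrast"`); `session_counts` optionally raises
#' the per-acquisition counts of the reproducibility sessions, and
#' `scan_delta_mua` sets the depth-scan perturbation (0 gives a null scan).
#'
#' @param ideal Collapse all ranges to the ideal instrument?
#' @param ... Named overrides of individual config entries.
#' @return A named list of class `"campaign_config"`.
#' @export
campaign_config <- function(ideal = FALSE, ...) {
  cfg <- list(
    type = "TD",                       # recycled over instruments
    fwhm_range_ps = c(150, 400),
    tail_fraction_range = c(0, 0.3),
    tail_tau_ps = 400,
    dark_rate_range_cps = c(200, 2e4),
    dnl_amp_range = c(0, 0.1),
    drift_amp_range_per_min = c(0, 2e-4),
    drift_t0_range_ps_per_min = c(0, 0.1),
    session_jitter_range = c(0, 0.03),
    responsivity_range_m2sr = c(1e-9, 1e-7),
    channel_width_ps = 10, n_channels = 1024,
    signal_counts = 5e5,               # standard 1-s acquisition
    kit_counts = 1e6, kit_reps = 3,
    stability_duration_min = 60, stability_period_s = 300,
    noise_levels = c(1e4, 1e5, 1e6), noise_reps = 10,
    n_sessions = 3, session_reps = 5, session_counts = NULL,
    depths_mm = seq(4, 28, by = 4), scan_reps = 20, scan_delta_mua = 0.17,
    kappa_p = 1e16, Pin_W = 1e-3, resp_tmeas_s = 1,
    dnl_counts_per_channel = 1e5, dark_tmeas_s = 10,
    tests = c("BIP", "Kit", "Stability", "Noise", "Reproducibility",
              "Contrast")
  )
  if (ideal) {
    cfg$fwhm_range_ps <- c(300, 300)
    cfg$tail_fraction_range <- c(0, 0)
    cfg$dark_rate_range_cps <- c(0, 0)
    cfg$dnl_amp_range <- c(0, 0)
    cfg$drift_amp_range_per_min <- c(0, 0)
    cfg$drift_t0_range_ps_per_min <- c(0, 0)
    cfg$session_jitter_range <- c(0, 0)
    cfg$responsivity_range_m2sr <- c(1e-8, 1e-8)
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "campaign_config")
}

.runif1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
.rlunif1 <- function(r) {
  if (r[1] == r[2]) return(r[1])
  if (r[1] <= 0) return(stats::runif(1, r[1], r[2]))
  10^stats::runif(1, log10(r[1]), log10(r[2]))
}

# Draw one virtual instrument from the config ranges.
.draw_instrument <- function(cfg) {
  n <- cfg$n_channels
  amp <- .runif1(cfg$dnl_amp_range)
  pat <- 1 + amp * sin(2 * pi * 8 * seq_len(n) / n)
  pat <- pat / mean(pat)
  instrument_model(
    irf = irf_model(fwhm_ps = .runif1(cfg$fwhm_range_ps),
                    tail_fraction = .runif1(cfg$tail_fraction_range),
                    tail_tau_ps = cfg$tail_tau_ps),
    channel_width_ps = cfg$channel_width_ps, n_channels = n,
    dark_rate_cps = .rlunif1(cfg$dark_rate_range_cps),
    dnl_pattern = pat,
    drift_amp_per_min = .runif1(cfg$drift_amp_range_per_min),
    drift_t0_ps_per_min = .runif1(cfg$drift_t0_range_ps_per_min),
    session_jitter = .runif1(cfg$session_jitter_range))
}

# Fit a list of DTOFs against one IRF; rows = repetitions. The count floor
# is relaxed: generator-driven series visit low count levels on purpose.
.fit_props_many <- function(dtofs, irf, floor_counts = 1e3, ...) {
  t(vapply(dtofs, function(d) {
    coef(fit_optical_properties(d, irf, floor_counts = floor_counts, ...))[
      c("mua", "musp")]
  }, numeric(2)))
}

#' Run a virtual multi-instrument measurement campaign
#'
#' Draws `n_instruments` virtual instruments from the configuration, runs
#' the full protocol battery on each — instrument-performance tests (IRF
#' width, responsivity, DNL, dark rate), the optical-property tests on the
#' virtual phantom kit (linearity, crosstalk, stability, noise,
#' reproducibility, and accuracy across the population), and the
#' depth-sensitivity contrast test — and returns the full figure-of-merit
#' table with its summary. CW-type instruments receive only the total-count
#' contrast test. Deterministic for a fixed seed.
#'
#' @param n_instruments Number of virtual instruments (>= 1; accuracy needs
#'   >= 3).
#' @param seed Integer seed.
#' @param config A [campaign_config()].
#' @param progress Print per-instrument progress lines?
#' @return List with `records` (the FOM table) and `summary`
#'   ([summarize_foms()] of it), class `"virtual_campaign"`.
#' @export
virtual_campaign <- function(n_instruments = 3, seed = 1,
                             config = campaign_config(), progress = FALSE) {
  stopifnot(inherits(config, "campaign_config"), n_instruments >= 1)
  cfg <- config
  types <- rep_len(cfg$type, n_instruments)
  props_b2 <- optical_props(0.05, 10)
  kit <- medphot_kit()
  recs <- list()
  b3 <- matrix(NA_real_, n_instruments, 2)
  add <- function(...) recs[[length(recs) + 1]] <<- fom_record(...)

  .with_seed(seed, {
    for (k in seq_len(n_instruments)) {
      id <- sprintf("virt%02d", k)
      if (progress) message("instrument ", id, " (", types[k], ")")
      inst <- .draw_instrument(cfg)
      true_resp <- .rlunif1(cfg$responsivity_range_m2sr)

      if (types[k] == "TD") {
        irf <- make_irf(inst, total_counts = 1e6)
        ## --- basic instrument performance
        if ("BIP" %in% cfg$tests) {
        add("BIP", "IRF", "FWHM", "All", irf_fwhm(irf), "ps", id)
        ri <- synthesize_responsivity_measurement(
          inst, cfg$kappa_p, cfg$Pin_W, cfg$resp_tmeas_s, true_resp)
        add("BIP", "Responsivity", "Responsivity", "All",
            responsivity(ri), "m2 sr", id)
        add("BIP", "DNL", "DNL", "All",
            dnl_eps(synthesize_dnl_measurement(inst,
                    cfg$dnl_counts_per_channel)), "-", id)
        add("BIP", "DarkCounts", "Dark counts", "All",
            dark_count_rate(synthesize_dark(inst, cfg$dark_tmeas_s)),
            "counts/s", id)
        }

        ## --- optical-property tests on the virtual kit
        if ("Kit" %in% cfg$tests) {
        kitfit <- kit
        kitfit$mua <- kitfit$musp <- NA_real_
        for (r in seq_len(nrow(kit))) {
          pr <- optical_props(kit$mua[r], kit$musp[r])
          ds <- lapply(seq_len(cfg$kit_reps), function(i)
            synthesize_dtof(pr, inst, signal_counts = cfg$kit_counts,
                            wavelength_nm = 800))
          est <- .fit_props_many(ds, irf)
          kitfit$mua[r] <- mean(est[, 1]); kitfit$musp[r] <- mean(est[, 2])
        }
        names(kitfit)[match(c("mua", "musp"), names(kitfit))] <-
          c("retrieved_tmp1", "retrieved_tmp2")
        kdf <- data.frame(label = kit$label, nominal_mua = kit$mua,
                          nominal_musp = kit$musp,
                          mua = kitfit$retrieved_tmp1,
                          musp = kitfit$retrieved_tmp2)
        b3[k, ] <- unlist(kdf[kdf$label == "B3", c("mua", "musp")])
        lin <- linearity_fom(kdf)
        add("MEDPHOT", "Linearity", "Linearity", "Mua", lin[["mua_pct"]], "%", id)
        add("MEDPHOT", "Linearity", "Linearity", "Mus", lin[["musp_pct"]], "%", id)
        ct <- crosstalk_fom(kdf)
        add("MEDPHOT", "Crosstalk", "Coupling", "Mua", ct$F_mus_to_mua, "-", id)
        add("MEDPHOT", "Crosstalk", "Coupling", "Mus", ct$F_mua_to_mus, "-", id)
        }

        if ("Stability" %in% cfg$tests) {
        st <- synthesize_stability_series(
          props_b2, inst, duration_min = cfg$stability_duration_min,
          period_s = cfg$stability_period_s,
          signal_counts = cfg$signal_counts)
        # timing drift must stay visible: pin t0 to the calibrated IRF
        est <- .fit_props_many(st$dtofs, irf, fit_t0 = FALSE)
        for (p in 1:2) {
          fm <- stability_fom(st$time_min, est[, p])
          tag <- c("Mua", "Mus")[p]
          add("MEDPHOT", "Stability", "Range", tag, fm[["range_pct"]], "%", id)
          add("MEDPHOT", "Stability", "Drift", tag,
              fm[["drift_pct_per_min"]], "%/min", id)
        }
        }

        if ("Noise" %in% cfg$tests) {
        ns <- synthesize_noise_series(props_b2, inst,
                                      count_levels = cfg$noise_levels,
                                      n_reps = cfg$noise_reps)
        ests <- lapply(ns$dtofs, .fit_props_many, irf = irf)
        for (p in 1:2) {
          nf <- noise_fom(cfg$noise_levels,
                          lapply(ests, function(e) e[, p]))
          add("MEDPHOT", "Noise", "CountsAt1pctCV", c("Mua", "Mus")[p],
              as.numeric(nf), "counts", id)
        }
        }

        if ("Reproducibility" %in% cfg$tests) {
        ss <- synthesize_sessions(props_b2, inst,
                                  n_sessions = cfg$n_sessions,
                                  n_reps = cfg$session_reps,
                                  signal_counts = if (is.null(cfg$session_counts))
                                    cfg$signal_counts else cfg$session_counts)
        sm <- t(vapply(ss$sessions, function(s)
          colMeans(.fit_props_many(s, irf)), numeric(2)))
        add("MEDPHOT", "Reproducibility", "CV", "Mua",
            reproducibility_fom(sm[, 1]), "%", id)
        add("MEDPHOT", "Reproducibility", "CV", "Mus",
            reproducibility_fom(sm[, 2]), "%", id)
        }

        ## --- depth-sensitivity contrast test
        if ("Contrast" %in% cfg$tests) {
        scan <- synthesize_depth_scan(inst, depths_mm = cfg$depths_mm,
                                      incl = inclusion_spec(10,
                                        delta_mua = cfg$scan_delta_mua),
                                      n_reps = cfg$scan_reps,
                                      signal_counts = cfg$signal_counts)
        fom <- neuropt_fom(depth_profile(scan))
        add("NEUROPT", "Contrast", "Contrast", "All", fom[["contrast"]], "-", id)
        add("NEUROPT", "Contrast", "CNR", "All", fom[["cnr"]], "-", id)
        }
      } else if ("Contrast" %in% cfg$tests) {
        ## CW-like instrument: only the total-count contrast test applies
        scan <- synthesize_depth_scan(inst, depths_mm = cfg$depths_mm,
                                      incl = inclusion_spec(10,
                                        delta_mua = cfg$scan_delta_mua),
                                      n_reps = cfg$scan_reps,
                                      signal_counts = cfg$signal_counts)
        fom <- neuropt_fom(cw_contrast(scan), window = "total")
        add("NEUROPT", "Contrast", "Contrast", "All", fom[["contrast"]], "-", id)
        add("NEUROPT", "Contrast", "CNR", "All", fom[["cnr"]], "-", id)
      }
    }
  })

  records <- do.call(rbind, recs)
  td <- which(types == "TD")
  if (length(td) >= 3 && "Kit" %in% cfg$tests && all(is.finite(b3[td, ]))) {
    for (p in 1:2) {
      acc <- accuracy_deviation(b3[td, p])
      for (i in seq_along(td))
        records <- rbind(records,
          fom_record("MEDPHOT", "Accuracy", "Deviation", c("Mua", "Mus")[p],
                     acc$deviation_pct[i], "%", sprintf("virt%02d", td[i])))
    }
  }
  structure(list(records = records, summary = summarize_foms(records)),
            class = "virtual_campaign")
}

#' @export
print.virtual_campaign <- function(x, ...) {
  cat("Virtual measurement campaign:",
      length(unique(x$records$instrument)), "instruments,",
      nrow(x$records), "FOM records\n\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
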