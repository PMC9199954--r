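# DTOF interchange format: one CSV per histogram (channel_index, counts)
# plus a JSON sidecar with the acquisition metadata. Round trips are
# bit-exact for counts and metadata.

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a DTOF to the interchange format
#'
#' Writes `<path>.csv` with columns `channel_index`, `counts` and a JSON
#' sidecar `<path>.json` holding `channel_width_ps`, `t0_channel`,
#' `acquisition_time_s`, `wavelength_nm`, `geometry`, `kind` and a
#' `provenance` block. Extra metadata keys passed through `...` are stored
#' verbatim.
#'
#' @param x A [dtof()].
#' @param path Output CSV path (sidecar path derived by swapping the
#'   extension).
#' @param provenance Optional named list (seed, generator version, ...).
#' @param ... Extra metadata keys to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_dtof <- function(x, path, provenance = NULL, ...) {
  stopifnot(inherits(x, "dtof"))
  utils::write.csv(data.frame(channel_index = seq_along(x$counts),
                              counts = as.integer(x$counts)),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(channel_width_ps = x$channel_width_ps,
               t0_channel = x$t0_channel,
               acquisition_time_s = x$acquisition_time_s,
               wavelength_nm = x$wavelength_nm,
               geometry = if (is.null(x$geom)) NULL else unclass(x$geom),
               kind = x$kind,
               provenance = provenance)
  extra <- list(...)
  if (length(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a DTOF from the interchange format
#'
#' @param path CSV path written by [write_dtof()]; the JSON sidecar must sit
#'   next to it.
#' @return A [dtof()]; metadata keys not part of the format are preserved in
#'   attribute `"extra_meta"`.
#' @export
read_dtof <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar for '", path, "'")
  tab <- utils::read.csv(path)
  if (!all(c("channel_index", "counts") %in% names(tab)))
    stop("malformed DTOF CSV: need columns channel_index, counts")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  geom <- NULL
  if (!is.null(meta$geometry) && length(meta$geometry)) {
    g <- meta$geometry
    geom <- geometry(mode = g$mode, rho_mm = g$rho_mm,
                     thickness_mm = if (is.null(g$thickness_mm) ||
                                        is.na(g$thickness_mm)) NULL
                                    else g$thickness_mm,
                     n_external = g$n_external)
  }
  known <- c("channel_width_ps", "t0_channel", "acquisition_time_s",
             "wavelength_nm", "geometry", "kind", "provenance")
  out <- dtof(tab$counts[order(tab$channel_index)],
              channel_width_ps = as.numeric(meta$channel_width_ps),
              t0_channel = as.integer(meta$t0_channel),
              acquisition_time_s = as.numeric(meta$acquisition_time_s),
              wavelength_nm = as.numeric(meta$wavelength_nm),
              geom = geom, kind = meta$kind)
  extra <- meta[setdiff(names(meta), known)]
  if (length(extra)) attr(out, "extra_meta") <- extra
  attr(out, "provenance") <- meta$provenance
  out
}
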