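#' Read and write sample-stream CSV files
#'
#' Streams are exchanged as comma-separated files with a mandatory header
#' \code{sample_index,counts} (UTF-8, \code{.} decimal): one row per
#' sample, counts as integers. The sample rate is not stored in the file;
#' it is supplied by the caller, because acquisition configuration lives
#' in the run configuration, not the data.
#'
#' @param path File path.
#' @param fs Sample rate in Hz to attach to the stream on read.
#' @param stream A \code{\link{sample_stream}} to write.
#' @return \code{read_stream}: a \code{\link{sample_stream}} (empty, with
#'   a warning, for a header-only file). \code{write_stream}: the path,
#'   invisibly.
#' @export
read_stream <- function(path, fs) {
  if (!file.exists(path)) stop_invalid(sprintf("stream file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("sample_index", "counts") %in% names(df))) {
    stop_invalid("stream CSV must have header `sample_index,counts`")
  }
  if (nrow(df) == 0L) {
    warning("stream file contains a header but no samples", call. = FALSE)
    return(sample_stream(numeric(0), fs))
  }
  counts <- suppressWarnings(as.numeric(df$counts))
  bad <- which(!grepl("^\\s*[+-]?[0-9]+\\s*$", df$counts) | is.na(counts))
  if (length(bad)) {
    stop_invalid(sprintf("non-integer count at line %d of %s: '%s'",
                         bad[1L] + 1L, path, df$counts[bad[1L]]))
  }
  sample_stream(counts, fs, metadata = list(path = path))
}

#' @rdname read_stream
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sample_stream"))
  df <- data.frame(sample_index = seq_along(stream$counts) - 1L,
                   counts = format(stream$counts, scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a demodulated amplitude trace
#'
#' Writes \code{time_s,R2} rows at the output interval; when a blank
#' amplitude is supplied an \code{R2_corrected} column with the
#' background-subtracted values is added, mirroring the bench software's
#' option of recording data both with and without background
#' subtraction.
#'
#' @param trace An \code{r_trace} from \code{\link{demodulate}}.
#' @param path File path.
#' @param blank Optional blank amplitude in a.u.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path, blank = NULL) {
  stopifnot(inherits(trace, "r_trace"))
  df <- data.frame(time_s = trace$times, R2 = trace$values)
  if (!is.null(blank)) {
    df$R2_corrected <- background_subtract(trace$values, blank_mean_of(blank))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration table
#'
#' Calibration series are exchanged as CSV with header
#' \code{concentration_M,r2_mean,r2_sd,n_readings}; the row with
#' concentration 0 is the blank.
#'
#' @param path File path.
#' @return A data frame of measurement records suitable for
#'   \code{\link{calibrate}}.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("calibration file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("concentration_M", "r2_mean", "r2_sd", "n_readings")
  if (!all(need %in% names(df))) {
    stop_invalid(sprintf("calibration CSV must have header `%s`",
                         paste(need, collapse = ",")))
  }
  check_records(df)
}

#' @rdname read_calibration
#' @param records A data frame of measurement records to write.
#' @export
write_calibration <- function(records, path) {
  records <- check_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a calibration result as JSON
#'
#' @param result A \code{\link{calibrate}} result.
#' @param path Optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
calibration_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "calibration_result"))
  json <- jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Frequency-rejection characterisation
#'
#' Quantifies how strongly the lock-in rejects off-frequency
#' interference: for each requested frequency a unit-amplitude tone is
#' demodulated, the settled amplitude is measured (the maximum over the
#' final \code{measure} seconds, a conservative bound since off-frequency
#' responses beat at the difference frequency), and the result is
#' expressed in dB relative to the response to an on-frequency tone. A
#' tone offset from the modulation frequency by \code{df >> fc} is
#' attenuated by roughly \code{n_stages * 20 * log10(df/fc)} dB.
#'
#' @param cfg A \code{\link{demod_config}}.
#' @param freqs Frequencies to probe, Hz, each in \code{(0, fs/2)}.
#' @param k Settling horizon in time constants before measuring.
#' @param measure Measurement window in seconds after settling.
#' @return A data frame with columns \code{freq_hz}, \code{response}
#'   (settled amplitude for a unit tone, a.u.) and \code{rel_db}
#'   (response relative to the on-frequency tone, dB; 0 dB at
#'   \code{f0}).
#' @export
characterize <- function(cfg, freqs, k = 10, measure = 1) {
  stopifnot(inherits(cfg, "demod_config"))
  if (any(freqs <= 0) || any(freqs >= cfg$fs / 2)) {
    stop_invalid("`freqs` must lie in (0, fs/2)")
  }
  f0 <- modulation_frequency(cfg)
  settle <- settling_time(cfg, k)
  n <- seq_len(round_half_up((settle + measure) * cfg$fs)) - 1
  settled_max <- function(f) {
    tone <- cos(2 * pi * f * n / cfg$fs)
    tr <- demodulate(tone, cfg)
    keep <- tr$times > settle
    max(tr$values[keep])
  }
  ref <- settled_max(f0)
  resp <- vapply(freqs, settled_max, numeric(1))
  data.frame(freq_hz = freqs, response = resp,
             rel_db = 20 * log10(resp / ref))
}
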