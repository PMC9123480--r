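#' A finite stream of ADC samples
#'
#' Container for a sampled photodetector signal: a numeric vector of ADC
#' counts acquired at a fixed sample rate, plus the parameters that
#' generated it (when it came from \code{\link{synthesize}}).
#'
#' @param counts Numeric vector of samples (integer ADC counts for
#'   simulated or acquired data; demodulation accepts any finite numeric
#'   values).
#' @param fs Sample rate in Hz.
#' @param metadata Optional named list describing how the stream was
#'   produced (concentration, seed, model parameters, ...).
#' @return An object of class \code{"sample_stream"}.
#' @seealso \code{\link{synthesize}}, \code{\link{demodulate}},
#'   \code{\link{read_stream}}
#' @export
sample_stream <- function(counts, fs, metadata = list()) {
  if (!is.numeric(counts)) stop_invalid("`counts` must be numeric")
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop_invalid("`counts` contains non-finite samples (corrupt input)")
  }
  if (!is_scalar_num(fs) || fs <= 0) stop_invalid("`fs` must be a positive number")
  structure(list(counts = as.numeric(counts), fs = fs, metadata = metadata),
            class = "sample_stream")
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("Sample stream: %d samples at %g Hz (%.4g s)\n",
              length(x$counts), x$fs, length(x$counts) / x$fs))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.sample_stream <- function(x) length(x$counts)
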