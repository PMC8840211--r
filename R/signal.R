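# Waveform conditioning: zero-phase FIR band-pass filtering, normalization,
# cubic-spline resampling, systolic peak detection, and extraction of
# normal-to-normal intervals (NNIs) for HRV analysis.

#' Uniformly sampled pulse trace
#'
#' Container for a real-valued series sampled uniformly at `rate` Hz, used
#' for both reference PPG and recovered rPPG waveforms.
#'
#' @param samples numeric vector, length >= 2.
#' @param rate sampling frequency in Hz, > 0.
#' @return an object of class `pulse_trace` with fields `samples` and `rate`.
#' @export
pulse_trace <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a pulse trace needs at least 2 samples")
  if (!is.finite(rate) || rate <= 0) stop("sampling rate must be positive")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "pulse_trace")
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("pulse trace: %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
plot.pulse_trace <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$rate
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "amplitude", ...)
  invisible(x)
}

as_pulse_trace <- function(x, rate = NULL) {
  if (inherits(x, "pulse_trace")) return(x)
  if (is.null(rate)) stop("a sampling rate is required for a bare series")
  pulse_trace(x, rate)
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase window-method FIR band-pass (Hamming window)
#' forward and backward, so the net phase is zero and peak times are not
#' shifted. The filter order defaults to about `3 * rate / lo`, rounded to
#' even, shortened if the trace is too short to support it. Output length
#' equals input length; the first and last second carry filter transients.
#'
#' @param trace a [pulse_trace()].
#' @param lo,hi band edges in Hz, `0 < lo < hi < rate/2`.
#' @param order optional FIR order override (even integer).
#' @return a filtered [pulse_trace()] at the same rate.
#' @export
bandpass <- function(trace, lo = 0.5, hi = 4, order = NULL) {
  trace <- as_pulse_trace(trace)
  nyq <- trace$rate / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop(sprintf("cutoffs must satisfy 0 < lo < hi < Nyquist (%g Hz)", nyq))
  }
  n <- length(trace$samples)
  if (is.null(order)) {
    order <- 2L * round(3 * trace$rate / lo / 2)
    # filtfilt needs the series comfortably longer than the filter
    order <- min(order, 2L * ((n - 1L) %/% 6L))
    order <- max(order, 4L)
  }
  b <- signal::fir1(order, c(lo, hi) / nyq, type = "pass")
  y <- signal::filtfilt(b, trace$samples)
  pulse_trace(y, trace$rate)
}

#' Z-normalize a trace
#'
#' Removes the mean and scales to unit standard deviation.
#'
#' @param trace a [pulse_trace()] (or numeric vector with `rate`).
#' @param rate sampling rate when `trace` is a bare vector.
#' @return normalized [pulse_trace()].
#' @export
znormalize <- function(trace, rate = NULL) {
  trace <- as_pulse_trace(trace, rate)
  s <- stats::sd(trace$samples)
  if (s == 0) stop("degenerate input: constant trace cannot be normalized")
  pulse_trace((trace$samples - mean(trace$samples)) / s, trace$rate)
}

#' Resample a trace on a uniform grid by cubic spline
#'
#' Interpolates the trace with a cubic spline onto a uniform grid at
#' `target_rate` Hz spanning the same time range. Used both to downsample
#' reference PPG to the video frame rate and to upsample traces to 256 Hz
#' for peak timing.
#'
#' @param trace a [pulse_trace()].
#' @param target_rate new sampling frequency in Hz.
#' @return resampled [pulse_trace()] at `target_rate`.
#' @export
resample_uniform <- function(trace, target_rate) {
  trace <- as_pulse_trace(trace)
  if (target_rate <= 0) stop("target rate must be positive")
  n <- length(trace$samples)
  if (n < 4L) stop("cubic-spline resampling needs at least 4 samples")
  t_in <- (seq_len(n) - 1) / trace$rate
  t_out <- seq(0, t_in[n], by = 1 / target_rate)
  y <- stats::spline(t_in, trace$samples, xout = t_out, method = "fmm")$y
  pulse_trace(y, target_rate)
}

#' Detect systolic peaks
#'
#' Finds local maxima whose topographic prominence is at least
#' `prominence_frac` times the trace standard deviation and which are at
#' least `rate / band[2]` samples apart (one peak per beat at the fastest
#' admissible heart rate). Optionally ignores the first and last
#' `edge_trim` seconds, where zero-phase filter transients live.
#'
#' @param trace a band-passed, normalized [pulse_trace()].
#' @param band admissible heart-rate band in Hz (default `c(0.5, 2.5)`).
#' @param prominence_frac minimum prominence as a fraction of `sd(trace)`.
#' @param edge_trim seconds excluded at each end (default 0).
#' @return an object of class `peak_set`: list with strictly increasing
#'   sample `indices` (1-based) and the trace `rate`. Empty if no peak
#'   qualifies.
#' @export
detect_peaks <- function(trace, band = c(0.5, 2.5), prominence_frac = 0.3,
                         edge_trim = 0) {
  trace <- as_pulse_trace(trace)
  x <- trace$samples
  n <- length(x)
  min_dist <- trace$rate / band[2]
  lo_i <- 1L + as.integer(ceiling(edge_trim * trace$rate))
  hi_i <- n - as.integer(ceiling(edge_trim * trace$rate))
  cand <- which(diff(sign(diff(x))) < 0) + 1L # strict rise, fall or plateau
  cand <- cand[cand >= max(2L, lo_i) & cand <= min(n - 1L, hi_i)]
  if (length(cand)) {
    prom <- peak_prominence(x, cand)
    cand <- cand[prom >= prominence_frac * stats::sd(x)]
  }
  # enforce the refractory distance, keeping higher peaks first
  if (length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  structure(list(indices = cand, rate = trace$rate), class = "peak_set")
}

# Topographic prominence of candidate maxima: height above the higher of
# the two key saddles separating the peak from taller terrain.
peak_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak set: %d peaks @ %g Hz\n", length(x$indices), x$rate))
  invisible(x)
}

#' Normal-to-normal intervals from detected peaks
#'
#' Converts consecutive peak indices to beat-to-beat intervals in
#' milliseconds: interval `i` is `(index[i+1] - index[i]) / rate * 1000`.
#' Optionally drops intervals outside the physiologic 250-2000 ms band.
#'
#' @param peaks a `peak_set` from [detect_peaks()], with at least 2 peaks.
#' @param physiologic_filter drop non-physiologic intervals (default FALSE;
#'   no outlier rejection is applied by default).
#' @return numeric vector of intervals in ms (class `nni`).
#' @export
peaks_to_nni <- function(peaks, physiologic_filter = FALSE) {
  if (!inherits(peaks, "peak_set")) stop("expected a peak_set")
  if (length(peaks$indices) < 2L) {
    stop("insufficient beats: need at least 2 peaks for an interval")
  }
  nni <- diff(peaks$indices) / peaks$rate * 1000
  if (physiologic_filter) nni <- nni[nni >= 250 & nni <= 2000]
  structure(nni, class = "nni")
}

#' Read / write a pulse trace as two-column text
#'
#' The on-disk format is CSV with columns `time_s` and `value`; the sampling
#' rate is recovered from the (uniform) time grid on read.
#'
#' @param trace a [pulse_trace()].
#' @param path file path.
#' @return `read_pulse_trace` returns a [pulse_trace()].
#' @export
write_pulse_trace <- function(trace, path) {
  trace <- as_pulse_trace(trace)
  df <- data.frame(time_s = (seq_along(trace$samples) - 1) / trace$rate,
                   value = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pulse_trace
#' @export
read_pulse_trace <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected two columns: time_s, value")
  dt <- diff(df[[1]])
  if (length(dt) < 1L || any(abs(dt - stats::median(dt)) > 1e-6)) {
    stop("time grid is not uniform")
  }
  pulse_trace(df[[2]], 1 / stats::median(dt))
}
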