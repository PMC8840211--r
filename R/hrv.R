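# Heart rate variability metrics from a normal-to-normal interval sequence:
# time-domain statistics, spectral (tachogram) band powers in normalized
# units, and agreement statistics between predicted and reference metrics.

#' Time-domain HRV metrics
#'
#' Computes, over `T` intervals in milliseconds: AVNN (mean interval), SDNN
#' (standard deviation with `T - 1` denominator), and RMSSD (root mean
#' square of the `T - 1` successive differences).
#'
#' @param nni numeric vector of NN intervals in ms, length >= 2.
#' @return an object of class `hrv_time`: list with `avnn`, `sdnn`, `rmssd`
#'   (all ms) and `n_intervals`.
#' @export
hrv_time_domain <- function(nni) {
  nni <- as.numeric(nni)
  if (length(nni) < 2L) stop("insufficient beats: need at least 2 intervals")
  structure(list(
    avnn = mean(nni),
    sdnn = stats::sd(nni),
    rmssd = sqrt(sum(diff(nni)^2) / (length(nni) - 1L)),
    n_intervals = length(nni)
  ), class = "hrv_time")
}

#' @export
print.hrv_time <- function(x, ...) {
  cat(sprintf("HRV time domain (%d intervals): AVNN %.1f ms, SDNN %.1f ms, RMSSD %.1f ms\n",
              x$n_intervals, x$avnn, x$sdnn, x$rmssd))
  invisible(x)
}

#' Frequency-domain HRV metrics
#'
#' Builds the tachogram (NN interval against the time of its closing beat),
#' resamples it uniformly at 4 Hz by cubic spline, removes the mean, and
#' estimates the power spectral density by Welch's method (Hann taper, 64-s
#' segments or the full record if shorter, 50% overlap). Band powers are
#' integrated over LF 0.04-0.15 Hz and HF 0.15-0.4 Hz and reported in
#' normalized units: `LFnu = LF / (LF + HF)`, `HFnu = HF / (LF + HF)`,
#' and the ratio `LF/HF`.
#'
#' @param nni numeric vector of NN intervals in ms; the record must span at
#'   least `min_duration` seconds for the LF band to be resolvable.
#' @param resample_rate tachogram resampling rate in Hz.
#' @param min_duration minimum record duration in s (default 30).
#' @return an object of class `hrv_freq`: list with `lfnu`, `hfnu`,
#'   `lf_hf`, and the raw band powers `lf_power`, `hf_power`.
#' @export
hrv_frequency_domain <- function(nni, resample_rate = 4, min_duration = 30) {
  nni <- as.numeric(nni)
  if (length(nni) < 2L) stop("insufficient beats: need at least 2 intervals")
  beat_t <- cumsum(nni) / 1000 # time of each interval's closing beat
  duration <- beat_t[length(beat_t)] - beat_t[1]
  if (duration < min_duration) {
    stop(sprintf("record too short for spectral analysis: %.1f s < %g s",
                 duration, min_duration))
  }
  grid <- seq(beat_t[1], beat_t[length(beat_t)], by = 1 / resample_rate)
  tach <- stats::spline(beat_t, nni, xout = grid, method = "fmm")$y
  tach <- tach - mean(tach)
  psd <- welch_psd(tach, resample_rate, segment_s = 64)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.4)
  if (lf + hf == 0) stop("degenerate spectrum: no power in LF + HF bands")
  structure(list(lfnu = lf / (lf + hf), hfnu = hf / (lf + hf),
                 lf_hf = lf / hf, lf_power = lf, hf_power = hf),
            class = "hrv_freq")
}

#' @export
print.hrv_freq <- function(x, ...) {
  cat(sprintf("HRV frequency domain: LFnu %.3f, HFnu %.3f, LF/HF %.3f\n",
              x$lfnu, x$hfnu, x$lf_hf))
  invisible(x)
}

# Welch power spectral density: Hann-tapered, mean-removed segments with
# 50% overlap, averaged one-sided periodograms.
welch_psd <- function(x, fs, segment_s = 64) {
  n <- length(x)
  nseg <- min(n, as.integer(round(segment_s * fs)))
  step <- max(1L, nseg %/% 2L)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))) # Hann
  u <- sum(w^2)
  starts <- seq(1L, n - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (length(starts) * fs * u)
  half <- seq_len(nseg %/% 2L + 1L)
  pxx <- pxx[half]
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, length(half))
  dbl[1] <- 1
  if (nseg %% 2L == 0L) dbl[length(dbl)] <- 1
  list(freq = (half - 1) * fs / nseg, psd = pxx * dbl, df = fs / nseg)
}

band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq < hi
  sum(psd$psd[sel]) * psd$df
}

#' Agreement statistics between paired metric values
#'
#' For paired predicted/reference values of one HRV metric across
#' recordings: mean absolute error, root-mean-square error, sample Pearson
#' correlation, and Bland-Altman bias with 95% limits of agreement
#' (`bias +- 1.96 sd(diff)`).
#'
#' @param pred,ref numeric vectors of equal length `n >= 2`.
#' @return an object of class `hrv_agreement`: list with `mae`, `rmse`,
#'   `r`, `bias`, `loa_lower`, `loa_upper`, `n`.
#' @export
hrv_agreement <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("paired lists must have equal length")
  if (length(pred) < 2L) stop("need at least 2 paired values")
  d <- pred - ref
  r <- if (stats::sd(pred) == 0 || stats::sd(ref) == 0) NA_real_
       else stats::cor(pred, ref)
  structure(list(
    mae = mean(abs(d)),
    rmse = sqrt(mean(d^2)),
    r = r,
    bias = mean(d),
    loa_lower = mean(d) - 1.96 * stats::sd(d),
    loa_upper = mean(d) + 1.96 * stats::sd(d),
    n = length(pred)
  ), class = "hrv_agreement")
}

#' @export
print.hrv_agreement <- function(x, ...) {
  cat(sprintf("agreement over %d pairs: MAE %.3f, RMSE %.3f, R %s, bias %.3f [%.3f, %.3f]\n",
              x$n, x$mae, x$rmse,
              if (is.na(x$r)) "NA" else sprintf("%.3f", x$r),
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Full HRV report for one interval sequence
#'
#' Convenience wrapper returning both time- and frequency-domain metrics as
#' a single one-row data.frame, suitable for CSV export.
#'
#' @param nni numeric vector of NN intervals in ms.
#' @param ... passed to [hrv_frequency_domain()].
#' @return data.frame with columns avnn, sdnn, rmssd, lfnu, hfnu, lf_hf.
#' @export
hrv_report <- function(nni, ...) {
  td <- hrv_time_domain(nni)
  fd <- hrv_frequency_domain(nni, ...)
  data.frame(avnn = td$avnn, sdnn = td$sdnn, rmssd = td$rmssd,
             lfnu = fd$lfnu, hfnu = fd$hfnu, lf_hf = fd$lf_hf)
}
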