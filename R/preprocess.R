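# forward-backward filtering with reflection padding: suppresses the start-up
# transients of zero-initial-condition filtering. `f_low` is the slowest
# critical frequency in Hz, which sets the needed pad length. Mirror (even)
# reflection suits pass filters (no spurious DC through a low high-pass edge);
# point-symmetric (odd) reflection suits stop filters, whose narrow stop band
# passes the broadband energy of a mirror cusp but not a smooth continuation.
.zp_filter <- function(flt, x, fs, f_low, reflect = c("even", "odd")) {
  reflect <- match.arg(reflect)
  n <- length(x)
  p <- min(n - 1, ceiling(10 * fs / f_low))
  if (p > 0) {
    xp <- if (reflect == "even") {
      c(x[(p + 1):2], x, x[(n - 1):(n - p)])
    } else {
      c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    }
  } else {
    xp <- x
  }
  y <- signal::filtfilt(flt, xp)
  y[(p + 1):(p + n)]
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the net response is zero-phase — a requirement for
#' downstream phase analysis. Attenuation one octave beyond either edge
#' exceeds 20 dB.
#'
#' @param rec A `continuous_recording`.
#' @param lo,hi Pass-band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return A new filtered `continuous_recording` (input is not modified).
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 45, order = 4) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= rec$fs / 2) {
    stop("upper edge ", hi, " Hz >= Nyquist (", rec$fs / 2, " Hz)", call. = FALSE)
  }
  flt <- signal::butter(order, c(lo, hi) * 2 / rec$fs, type = "pass")
  out <- t(apply(rec$data, 1, function(x) .zp_filter(flt, x, rec$fs, lo)))
  .with_data(rec, out)
}

#' Zero-phase notch (band-stop) filter
#'
#' Second-order Butterworth band-stop of half-width `width` Hz around `freq`,
#' applied forward-backward. Attenuation at `freq` exceeds 20 dB while signals
#' 5 Hz away are attenuated by less than 1 dB.
#'
#' @param rec A `continuous_recording`.
#' @param freq Notch center frequency in Hz (mains interference, default 50).
#' @param width Half-width of the stop band in Hz (default 2).
#' @return A new filtered `continuous_recording`.
#' @export
notch_filter <- function(rec, freq = 50, width = 2) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (!(freq > 0 && freq < rec$fs / 2)) {
    stop("notch frequency must lie in (0, Nyquist)", call. = FALSE)
  }
  flt <- signal::butter(2, c(freq - width, freq + width) * 2 / rec$fs, type = "stop")
  out <- t(apply(rec$data, 1, function(x) .zp_filter(flt, x, rec$fs, width, reflect = "odd")))
  .with_data(rec, out)
}

#' Re-reference to the average of the two mastoids
#'
#' Subtracts the mean of the left and right mastoid channels from every other
#' channel; the mastoid channels themselves are dropped from the output.
#'
#' @param rec A `continuous_recording`.
#' @param left,right Mastoid channel labels (defaults `"M1"`, `"M2"`).
#' @return A new re-referenced `continuous_recording` without mastoid rows.
#' @export
rereference_mastoids <- function(rec, left = "M1", right = "M2") {
  stopifnot(inherits(rec, "continuous_recording"))
  for (lab in c(left, right)) {
    if (!lab %in% rec$labels) {
      stop("mastoid channel not found in recording: ", lab, call. = FALSE)
    }
  }
  ref <- (rec$data[left, ] + rec$data[right, ]) / 2
  keep <- setdiff(rec$labels, c(left, right))
  out <- sweep(rec$data[keep, , drop = FALSE], 2, ref, "-")
  .with_data(rec, out, labels = keep)
}

#' Downsample with anti-alias filtering
#'
#' Low-pass filters at 80% of the target Nyquist (zero-phase, sixth-order
#' Butterworth) and decimates by the integer factor `fs / target_fs`. The
#' output has `floor(n * target_fs / fs)` samples.
#'
#' @param rec A `continuous_recording`.
#' @param target_fs Target sampling rate in Hz; must divide `fs`.
#' @return A new `continuous_recording` at `target_fs`.
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (target_fs >= rec$fs) stop("target_fs must be below fs", call. = FALSE)
  fac <- rec$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) {
    stop("target_fs must divide fs (rational resampling not supported)",
         call. = FALSE)
  }
  fac <- round(fac)
  cutoff <- 0.8 * target_fs / 2
  flt <- signal::butter(6, cutoff * 2 / rec$fs, type = "low")
  filt <- t(apply(rec$data, 1, function(x) .zp_filter(flt, x, rec$fs, cutoff)))
  n_out <- floor(ncol(rec$data) * target_fs / rec$fs)
  idx <- 1 + (seq_len(n_out) - 1) * fac
  .with_data(rec, filt[, idx, drop = FALSE], fs = target_fs)
}

#' Cut a recording into consecutive fixed-length epochs
#'
#' Non-overlapping epochs anchored at the first sample; a trailing partial
#' epoch is discarded. All epochs start out retained.
#'
#' @param rec A `continuous_recording`.
#' @param length_ms Epoch duration in milliseconds (default 1000).
#' @return An `epoched_recording`.
#' @export
epoch_recording <- function(rec, length_ms = 1000) {
  stopifnot(inherits(rec, "continuous_recording"))
  spe <- round(rec$fs * length_ms / 1000)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1) {
    stop("recording shorter than one epoch (", length_ms, " ms)", call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(n_ep, nrow(rec$data), spe))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
  }
  epoched_recording(arr, rec$fs, length_ms, rec$labels,
                    role = rec$role, condition = rec$condition,
                    dyad_id = rec$dyad_id)
}

#' Reject epochs by peak amplitude
#'
#' Marks an epoch as not retained when any sample on any channel exceeds
#' `threshold_uv` in absolute value. Data are left untouched; only the
#' retained mask changes (joint with any prior rejections).
#'
#' @param ep An `epoched_recording`.
#' @param threshold_uv Rejection threshold in microvolts (default 75).
#' @return A new `epoched_recording` with an updated retained mask.
#' @export
reject_amplitude <- function(ep, threshold_uv = 75) {
  stopifnot(inherits(ep, "epoched_recording"), threshold_uv > 0)
  peak <- apply(abs(ep$data), 1, max)
  out <- ep
  out$retained <- ep$retained & (peak <= threshold_uv)
  out
}

#' Default preprocessing parameters
#'
#' Band-pass 1-45 Hz, 50 Hz notch, mastoid re-reference, downsample to
#' 250 Hz, 1000 ms epochs, +/-75 microvolt rejection.
#'
#' @return Named list of preprocessing parameters.
#' @export
preprocess_defaults <- function() {
  list(band_lo = 1, band_hi = 45, notch_hz = 50, target_fs = 250,
       epoch_ms = 1000, reject_uv = 75, mastoid_left = "M1",
       mastoid_right = "M2")
}

#' Full preprocessing chain for one recording
#'
#' Applies, in order: band-pass filter, notch filter, mastoid re-reference
#' (skipped when the mastoid channels are absent), downsampling, epoching and
#' amplitude rejection. An optional `clean_hook` runs on the continuous
#' recording after re-referencing — the insertion point for externally
#' ICA-cleaned data; the pipeline does not implement ICA itself.
#'
#' @param rec A `continuous_recording`.
#' @param params List of parameters as from [preprocess_defaults()].
#' @param clean_hook Optional `function(rec) -> rec` applied before
#'   downsampling.
#' @return An `epoched_recording`.
#' @export
preprocess <- function(rec, params = preprocess_defaults(), clean_hook = NULL) {
  p <- utils::modifyList(preprocess_defaults(), params)
  out <- bandpass_filter(rec, p$band_lo, p$band_hi)
  out <- notch_filter(out, p$notch_hz)
  if (all(c(p$mastoid_left, p$mastoid_right) %in% out$labels)) {
    out <- rereference_mastoids(out, p$mastoid_left, p$mastoid_right)
  }
  if (!is.null(clean_hook)) out <- clean_hook(out)
  if (p$target_fs < out$fs) out <- downsample(out, p$target_fs)
  ep <- epoch_recording(out, p$epoch_ms)
  reject_amplitude(ep, p$reject_uv)
}
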