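#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples, amplitudes in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (unique, one per row of `data`).
#' @param role `"speaker"` or `"listener"`.
#' @param condition `"happy"`, `"sad"`, `"neutral"` or `"rest"`.
#' @param dyad_id Dyad identifier.
#' @return Object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, labels,
                                 role = c("speaker", "listener"),
                                 condition = c("happy", "sad", "neutral", "rest"),
                                 dyad_id = NA_character_) {
  role <- match.arg(role)
  condition <- match.arg(condition)
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(fs), length(fs) == 1, fs > 0)
  if (length(labels) != nrow(data)) {
    stop("label count (", length(labels), ") != channel count (",
         nrow(data), ")", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, role = role,
         condition = condition, dyad_id = dyad_id),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %s/%s dyad=%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$role, x$condition, x$dyad_id, nrow(x$data), ncol(x$data),
              x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct an epoched recording
#'
#' @param data Numeric array, epochs x channels x samples_per_epoch.
#' @param fs Sampling rate in Hz.
#' @param epoch_ms Epoch duration in milliseconds.
#' @param labels Channel labels.
#' @param retained Logical mask over epochs (default all `TRUE`).
#' @param role,condition,dyad_id Provenance carried over from the source
#'   recording.
#' @return Object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, epoch_ms, labels, retained = NULL,
                              role = "speaker", condition = "rest",
                              dyad_id = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spe <- round(fs * epoch_ms / 1000)
  if (dim(data)[3] != spe) {
    stop("samples per epoch (", dim(data)[3], ") != round(fs * epoch_ms / 1000) = ",
         spe, call. = FALSE)
  }
  if (dim(data)[2] != length(labels)) stop("label/channel mismatch", call. = FALSE)
  if (is.null(retained)) retained <- rep(TRUE, dim(data)[1])
  stopifnot(is.logical(retained), length(retained) == dim(data)[1])
  structure(
    list(data = data, fs = fs, epoch_ms = epoch_ms, labels = labels,
         retained = retained, role = role, condition = condition,
         dyad_id = dyad_id),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %s/%s: %d epochs (%d retained) x %d ch x %d samples @ %g Hz\n",
              x$role, x$condition, dim(x$data)[1], sum(x$retained),
              dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

#' Number of retained epochs
#' @param ep An `epoched_recording` or `phase_series`.
#' @return Integer count.
#' @export
n_retained <- function(ep) sum(ep$retained)

# internal: rebuild a recording with new data, everything else carried over
.with_data <- function(rec, data, fs = rec$fs, labels = rec$labels) {
  continuous_recording(data, fs, labels, rec$role, rec$condition, rec$dyad_id)
}
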