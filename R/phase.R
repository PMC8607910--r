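#' Analytic signal via the one-sided spectrum
#'
#' Complex extension of a real signal whose argument is the instantaneous
#' phase: negative-frequency components are zeroed and positive ones doubled
#' in the discrete Fourier domain.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Extract band-limited instantaneous phase from epoched data
#'
#' Per epoch and channel the signal is band-pass filtered (zero-phase
#' Butterworth) and the angle of the analytic signal taken (`method =
#' "analytic"`, the default), or convolved with a complex Morlet wavelet at
#' the band center (`method = "morlet"`). `edge_ms` of samples at each epoch
#' edge are flagged unreliable (filter transients) and excluded from
#' phase-locking sums downstream.
#'
#' @param ep An `epoched_recording`.
#' @param band Band designator (see [as_band()]); default theta.
#' @param edge_ms Edge exclusion per epoch side in ms (default 100).
#' @param method Phase extraction method.
#' @param n_cycles Morlet wavelet width in cycles (only for `"morlet"`).
#' @return Object of class `phase_series` with fields `phases`
#'   (epochs x channels x samples, radians in (-pi, pi]), `band`, `fs`,
#'   `labels`, `retained` and logical sample mask `valid`.
#' @export
extract_phase <- function(ep, band = "theta", edge_ms = 100,
                          method = c("analytic", "morlet"), n_cycles = 6) {
  stopifnot(inherits(ep, "epoched_recording"))
  method <- match.arg(method)
  band <- as_band(band)
  if (band$hi >= ep$fs / 2) stop("band exceeds Nyquist", call. = FALSE)
  if (!any(ep$retained)) {
    stop("empty after rejection: no retained epochs", call. = FALSE)
  }
  d <- dim(ep$data)
  spe <- d[3]
  edge <- round(ep$fs * edge_ms / 1000)
  if (2 * edge >= spe) stop("edge exclusion leaves no valid samples", call. = FALSE)
  valid <- rep(TRUE, spe)
  if (edge > 0) valid[c(seq_len(edge), (spe - edge + 1):spe)] <- FALSE

  flt <- signal::butter(4, c(band$lo, band$hi) * 2 / ep$fs, type = "pass")
  wav <- if (method == "morlet") .morlet_kernel((band$lo + band$hi) / 2, ep$fs, n_cycles)
  phases <- array(NA_real_, dim = d)
  for (e in seq_len(d[1])) {
    if (!ep$retained[e]) next
    for (ch in seq_len(d[2])) {
      x <- ep$data[e, ch, ]
      if (stats::sd(x) < .Machine$double.eps^0.5) {
        stop("degenerate signal: epoch ", e, " channel ", ep$labels[ch],
             " is (near-)constant, phase undefined", call. = FALSE)
      }
      z <- if (method == "analytic") {
        analytic_signal(.zp_filter(flt, x, ep$fs, band$lo))
      } else {
        .conv_same(x - mean(x), wav)
      }
      phases[e, ch, ] <- Arg(z)
    }
  }
  structure(
    list(phases = phases, band = band, fs = ep$fs, labels = ep$labels,
         retained = ep$retained, valid = valid, role = ep$role,
         condition = ep$condition, dyad_id = ep$dyad_id),
    class = "phase_series"
  )
}

#' Construct a phase series directly from phase arrays
#'
#' Used by the synthetic generator, which knows the ground-truth phases
#' exactly; all samples are valid.
#'
#' @param phases Array epochs x channels x samples, radians.
#' @param band Band designator.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels.
#' @param role,condition,dyad_id Provenance.
#' @return A `phase_series`.
#' @export
phase_series <- function(phases, band, fs, labels,
                         role = "speaker", condition = "rest",
                         dyad_id = NA_character_) {
  stopifnot(is.array(phases), length(dim(phases)) == 3,
            dim(phases)[2] == length(labels))
  structure(
    list(phases = .wrap_pi(phases), band = as_band(band), fs = fs,
         labels = labels, retained = rep(TRUE, dim(phases)[1]),
         valid = rep(TRUE, dim(phases)[3]), role = role,
         condition = condition, dyad_id = dyad_id),
    class = "phase_series"
  )
}

# wrap to (-pi, pi]
.wrap_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

.morlet_kernel <- function(f0, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f0)
  t <- seq(-3 * sigma_t, 3 * sigma_t, by = 1 / fs)
  w <- exp(2i * pi * f0 * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# centered complex convolution, output length = length(x)
.conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  full <- stats::convolve(c(x, numeric(m - 1)), rev(Conj(k)), type = "open")
  ofs <- (m - 1) %/% 2
  full[(ofs + 1):(ofs + n)]
}

#' Phase-locking value of two phase sample vectors
#'
#' `PLV = (1/N) |sum_t exp(i (phi_i(t) - phi_k(t)))|`: the modulus of the
#' mean unit phasor of the phase difference. 1 means perfect locking; for
#' independent phases the value decays to 0 as `N^(-1/2)`.
#'
#' @param phi_i,phi_k Numeric vectors of phases in radians, equal length >= 1.
#' @return Scalar in `[0, 1]`.
#' @export
plv_pair <- function(phi_i, phi_k) {
  if (length(phi_i) != length(phi_k)) {
    stop("phase vectors must have equal length", call. = FALSE)
  }
  stopifnot(length(phi_i) >= 1)
  min(1, Mod(mean(exp(1i * (phi_i - phi_k)))))
}

#' Speaker x listener PLV matrix
#'
#' Entry (i, k) is the phase-locking value between speaker channel i and
#' listener channel k. In the default `"within_epoch"` mode the PLV is
#' computed over valid time samples within each jointly retained epoch and
#' then averaged across epochs; `"across_epoch"` instead computes the PLV
#' across epochs at each fixed latency and averages over latencies. Epoch
#' counts are equalized by truncation to the shorter series.
#'
#' @param speaker,listener `phase_series` objects with matching band, fs and
#'   epoch length.
#' @param mode Averaging convention (see Details).
#' @return Object of class `plv_matrix` with `values` (speaker channels x
#'   listener channels, all in `[0, 1]`), `band`, `dyad_id`, `condition`.
#' @export
plv_matrix <- function(speaker, listener, mode = c("within_epoch", "across_epoch")) {
  mode <- match.arg(mode)
  stopifnot(inherits(speaker, "phase_series"), inherits(listener, "phase_series"))
  if (speaker$band$name != listener$band$name || speaker$fs != listener$fs) {
    stop("phase series disagree on band or sampling rate", call. = FALSE)
  }
  if (dim(speaker$phases)[3] != dim(listener$phases)[3]) {
    stop("phase series disagree on epoch length", call. = FALSE)
  }
  n_ep <- min(dim(speaker$phases)[1], dim(listener$phases)[1])
  joint <- speaker$retained[seq_len(n_ep)] & listener$retained[seq_len(n_ep)]
  if (!any(joint)) stop("empty after rejection: no jointly retained epochs",
                        call. = FALSE)
  valid <- speaker$valid & listener$valid
  eps_idx <- which(joint)
  ns <- dim(speaker$phases)[2]
  nl <- dim(listener$phases)[2]
  acc <- matrix(0, ns, nl)
  if (mode == "within_epoch") {
    nv <- sum(valid)
    for (e in eps_idx) {
      es <- exp(1i * speaker$phases[e, , valid, drop = FALSE][1, , , drop = TRUE])
      el <- exp(1i * listener$phases[e, , valid, drop = FALSE][1, , , drop = TRUE])
      es <- matrix(es, ns, nv); el <- matrix(el, nl, nv)
      acc <- acc + Mod(es %*% Conj(t(el))) / nv
    }
    vals <- acc / length(eps_idx)
  } else {
    n_e <- length(eps_idx)
    for (t in which(valid)) {
      es <- matrix(exp(1i * speaker$phases[eps_idx, , t, drop = FALSE]), n_e, ns)
      el <- matrix(exp(1i * listener$phases[eps_idx, , t, drop = FALSE]), n_e, nl)
      acc <- acc + Mod(t(es) %*% Conj(el)) / n_e
    }
    vals <- acc / sum(valid)
  }
  vals <- pmin(vals, 1)
  dimnames(vals) <- list(speaker$labels, listener$labels)
  structure(
    list(values = vals, band = speaker$band,
         dyad_id = speaker$dyad_id, condition = speaker$condition),
    class = "plv_matrix"
  )
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> dyad=%s cond=%s band=%s: %d x %d, mean %.3f\n",
              x$dyad_id, x$condition, x$band$name, nrow(x$values),
              ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Mean PLV over all channel pairs inside one ROI
#'
#' Averages `m$values[i, k]` over all speaker channels i and listener
#' channels k whose labels both belong to the named ROI.
#'
#' @param m A `plv_matrix`.
#' @param roi ROI name.
#' @param rois ROI map (default [default_roi_map()]).
#' @param homologous_only If `TRUE`, average only pairs with identical
#'   speaker and listener labels.
#' @return Scalar mean PLV.
#' @export
roi_mean_plv <- function(m, roi, rois = default_roi_map(), homologous_only = FALSE) {
  stopifnot(inherits(m, "plv_matrix"))
  if (!roi %in% names(rois)) stop("unknown ROI: ", roi, call. = FALSE)
  labs <- rois[[roi]]
  rs <- intersect(rownames(m$values), labs)
  cs <- intersect(colnames(m$values), labs)
  if (!length(rs) || !length(cs)) {
    stop("ROI ", roi, " has no channels present in the PLV matrix", call. = FALSE)
  }
  if (homologous_only) {
    both <- intersect(rs, cs)
    return(mean(m$values[cbind(both, both)]))
  }
  mean(m$values[rs, cs, drop = FALSE])
}

#' Emotion-minus-neutral synchrony contrast
#'
#' @param emotion_mean,neutral_mean ROI-mean PLV values in `[0, 1]`.
#' @return `emotion_mean - neutral_mean` (may be negative).
#' @export
delta_plv <- function(emotion_mean, neutral_mean) {
  stopifnot(all(emotion_mean >= 0 & emotion_mean <= 1),
            all(neutral_mean >= 0 & neutral_mean <= 1))
  emotion_mean - neutral_mean
}

#' Per-dyad ROI summary of emotion and neutral PLV
#'
#' @param plv_emotion,plv_neutral `plv_matrix` objects for the emotion and
#'   neutral condition of one dyad.
#' @param rois ROI map.
#' @return One-row data frame: `dyad_id`, per-ROI `plv_<roi>_emotion`,
#'   `plv_<roi>_neutral` and `dplv_<roi>`.
#' @export
dyad_roi_summary <- function(plv_emotion, plv_neutral, rois = default_roi_map()) {
  out <- list(dyad_id = plv_emotion$dyad_id)
  for (roi in names(rois)) {
    em <- roi_mean_plv(plv_emotion, roi, rois)
    ne <- roi_mean_plv(plv_neutral, roi, rois)
    out[[paste0("plv_", roi, "_emotion")]] <- em
    out[[paste0("plv_", roi, "_neutral")]] <- ne
    out[[paste0("dplv_", roi)]] <- delta_plv(em, ne)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
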