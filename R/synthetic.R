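#' Draw from the von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on `(-pi, pi]`.
#'
#' @param n Number of draws.
#' @param kappa Concentration parameter, `>= 0`.
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- ceiling((n - got) / 0.6)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1))
    k <- min(length(th), n - got)
    if (k > 0) out[(got + 1):(got + k)] <- th[seq_len(k)]
    got <- got + k
  }
  out
}

#' Population PLV of a von Mises phase difference
#'
#' For a phase difference distributed von Mises with concentration `kappa`,
#' the mean resultant length — the population phase-locking value — is the
#' modified-Bessel ratio `I1(kappa) / I0(kappa)`.
#'
#' @param kappa Concentration(s), `>= 0`.
#' @return PLV value(s) in `[0, 1)`.
#' @export
plv_from_kappa <- function(kappa) {
  stopifnot(all(kappa >= 0))
  vapply(kappa, function(k) {
    if (k == 0) return(0)
    if (k > 1e5) {
      # asymptotic expansion; besselI loses precision at very large argument
      return(1 - 1 / (2 * k) - 1 / (8 * k^2))
    }
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }, numeric(1))
}

#' Invert the Bessel ratio: concentration for a target population PLV
#'
#' @param r Target PLV value(s) in `[0, 1)`.
#' @return Concentration(s) `kappa >= 0`.
#' @export
kappa_from_plv <- function(r) {
  stopifnot(all(r >= 0), all(r < 1))
  vapply(r, function(ri) {
    if (ri < 1e-12) return(0)
    stats::uniroot(function(k) plv_from_kappa(k) - ri,
                   lower = 1e-8, upper = 1e8, tol = 1e-10)$root
  }, numeric(1))
}

#' Specify phase coupling for one ROI
#'
#' @param roi ROI name (must exist in `rois`).
#' @param kappa von Mises concentration of the speaker-listener phase
#'   difference (dimensionless, `>= 0`); the induced population PLV is
#'   `I1(kappa)/I0(kappa)`.
#' @param band Band designator; the carrier must lie inside it.
#' @param carrier_hz Oscillation center frequency in Hz.
#' @param rois ROI map used for validation.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(roi, kappa, band = "theta", carrier_hz = 5.5,
                          rois = default_roi_map()) {
  band <- as_band(band)
  if (!roi %in% names(rois)) stop("unknown ROI: ", roi, call. = FALSE)
  stopifnot(kappa >= 0)
  if (carrier_hz < band$lo || carrier_hz > band$hi) {
    stop("carrier ", carrier_hz, " Hz outside band [", band$lo, ", ",
         band$hi, "] Hz", call. = FALSE)
  }
  structure(list(roi = roi, kappa = kappa, band = band,
                 carrier_hz = carrier_hz),
            class = "coupling_spec")
}

# 1/f-shaped Gaussian noise band-limited to [lo, hi] Hz, sd scaled to `sd`
.pink_noise <- function(n, fs, sd = 1, lo = 1, hi = 45) {
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  amp <- ifelse(f >= lo & f <= hi, 1 / sqrt(pmax(f, lo)), 0)
  ph <- stats::runif(length(amp), 0, 2 * pi)
  half <- amp * exp(1i * ph)
  spec <- c(half, Conj(rev(half[2:(length(half) - (n %% 2 == 0))])))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

#' Generate one synthetic speaker-listener dyad
#'
#' Channels inside each coupled ROI carry a narrowband carrier oscillation;
#' the listener's copy lags the speaker's by a per-sample von Mises phase
#' difference with concentration `kappa`, so the population PLV of a coupled
#' pair is `I1(kappa)/I0(kappa)`. All channels additionally carry independent
#' 1/f-shaped noise band-limited to 1-45 Hz. The exact ground-truth phases of
#' every coupled channel are attached (attribute `"truth"`), retrievable with
#' [dyad_true_phases()].
#'
#' @param coupling List of [coupling_spec()] objects (at most one per ROI).
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Recording length in seconds, `>= 4`.
#' @param montage Channel labels (default [default_montage()]).
#' @param noise_sd Background noise SD in microvolts.
#' @param osc_amp Carrier amplitude in microvolts.
#' @param artifact_fraction Fraction of 1 s blocks receiving a rectangular
#'   high-amplitude artifact (exercises amplitude rejection; default 0).
#' @param artifact_uv Artifact amplitude in microvolts (default 120).
#' @param rois ROI map.
#' @param dyad_id Identifier stamped on both recordings.
#' @param condition Condition tag.
#' @param seed Integer seed (optional; caller-managed RNG when `NULL`).
#' @return List with elements `speaker` and `listener`
#'   (`continuous_recording`s), class `coupled_dyad`.
#' @export
make_coupled_dyad <- function(coupling, fs = 250, duration = 240,
                              montage = default_montage(), noise_sd = 20,
                              osc_amp = 10, artifact_fraction = 0,
                              artifact_uv = 120, rois = default_roi_map(),
                              dyad_id = "dyad", condition = "happy",
                              seed = NULL) {
  if (duration < 4) stop("duration must be at least 4 s", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(coupling, "coupling_spec")) coupling <- list(coupling)
  stopifnot(all(vapply(coupling, inherits, logical(1), "coupling_spec")))
  covered <- vapply(coupling, `[[`, character(1), "roi")
  if (anyDuplicated(covered)) stop("more than one coupling spec for an ROI",
                                   call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  nc <- length(montage)
  spk <- matrix(0, nc, n, dimnames = list(montage, NULL))
  lst <- matrix(0, nc, n, dimnames = list(montage, NULL))
  truth_s <- matrix(NA_real_, nc, n, dimnames = list(montage, NULL))
  truth_l <- matrix(NA_real_, nc, n, dimnames = list(montage, NULL))
  for (ch in seq_len(nc)) {
    spk[ch, ] <- .pink_noise(n, fs, noise_sd)
    lst[ch, ] <- .pink_noise(n, fs, noise_sd)
  }
  for (cs in coupling) {
    chans <- intersect(montage, rois[[cs$roi]])
    if (!length(chans)) {
      stop("ROI ", cs$roi, " has no channels in the montage", call. = FALSE)
    }
    for (ch in chans) {
      phi0 <- stats::runif(1, 0, 2 * pi)
      theta <- 2 * pi * cs$carrier_hz * t + phi0
      delta <- rvonmises(n, cs$kappa)
      spk[ch, ] <- spk[ch, ] + osc_amp * cos(theta)
      lst[ch, ] <- lst[ch, ] + osc_amp * cos(theta - delta)
      truth_s[ch, ] <- .wrap_pi(theta)
      truth_l[ch, ] <- .wrap_pi(theta - delta)
    }
  }
  if (artifact_fraction > 0) {
    blocks <- floor(duration)
    hit <- which(stats::runif(blocks) < artifact_fraction)
    for (b in hit) {
      i0 <- (b - 1) * fs + 1
      ch <- sample(nc, 1)
      side <- sample(c("spk", "lst"), 1)
      seg <- i0:(i0 + round(fs / 10))
      if (side == "spk") spk[ch, seg] <- spk[ch, seg] + artifact_uv
      else lst[ch, seg] <- lst[ch, seg] + artifact_uv
    }
  }
  out <- structure(
    list(
      speaker = continuous_recording(spk, fs, montage, "speaker", condition, dyad_id),
      listener = continuous_recording(lst, fs, montage, "listener", condition, dyad_id)
    ),
    class = "coupled_dyad"
  )
  attr(out, "truth") <- list(speaker = truth_s, listener = truth_l,
                             coupling = coupling, fs = fs)
  out
}

#' Ground-truth phase series of a synthetic dyad
#'
#' Segments the generator's exact coupled-channel phases into epochs,
#' returning one `phase_series` per participant (coupled channels only; all
#' samples valid). This is the calibration surface: the PLV estimator applied
#' to these series measures the generator's von Mises coupling without
#' filter-induced smoothing.
#'
#' @param dyad A `coupled_dyad`.
#' @param epoch_ms Epoch length in ms (default 1000).
#' @return List with `speaker` and `listener` `phase_series`.
#' @export
dyad_true_phases <- function(dyad, epoch_ms = 1000) {
  stopifnot(inherits(dyad, "coupled_dyad"))
  tr <- attr(dyad, "truth")
  coupled <- rownames(tr$speaker)[rowSums(!is.na(tr$speaker)) > 0]
  if (!length(coupled)) stop("dyad has no coupled channels", call. = FALSE)
  band <- tr$coupling[[1]]$band
  spe <- round(tr$fs * epoch_ms / 1000)
  n_ep <- floor(ncol(tr$speaker) / spe)
  cut <- function(m) {
    arr <- array(NA_real_, c(n_ep, length(coupled), spe))
    for (e in seq_len(n_ep)) {
      arr[e, , ] <- m[coupled, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
    }
    arr
  }
  list(
    speaker = phase_series(cut(tr$speaker), band, tr$fs, coupled, "speaker",
                           dyad$speaker$condition, dyad$speaker$dyad_id),
    listener = phase_series(cut(tr$listener), band, tr$fs, coupled, "listener",
                            dyad$listener$condition, dyad$listener$dyad_id)
  )
}

#' Generate a unidirectionally coupled pair of autoregressive series
#'
#' `x` is unit-variance white noise; `y_t = drive * x_{t-order} + e_t` with
#' unit-variance innovations and no feedback from `y` to `x`. At `order = 1`
#' the population Granger statistic is exactly
#' `F(x -> y) = ln(1 + drive^2 * var(x))` and `F(y -> x) = 0`.
#'
#' @param n_samples Series length, `>= 100 * order`.
#' @param drive Coupling coefficient, `|drive| < 1`.
#' @param order Drive lag (default 1).
#' @param seed Integer seed (optional).
#' @return List with numeric vectors `x` and `y`.
#' @export
make_var_dyad <- function(n_samples, drive, order = 1, seed = NULL) {
  if (abs(drive) >= 1) {
    stop("unstable coupling configuration: |drive| must be < 1", call. = FALSE)
  }
  stopifnot(order >= 1)
  if (n_samples < 100 * order) {
    stop("n_samples must be at least 100 * order", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n_samples)
  y <- stats::rnorm(n_samples)
  idx <- (order + 1):n_samples
  y[idx] <- y[idx] + drive * x[idx - order]
  list(x = x, y = y, drive = drive, order = order)
}

#' Specify a two-group synthetic cohort
#'
#' Defaults reproduce the study conditions of a two-group speaker-listener
#' design: 15 happy and 17 sad dyads; per-ROI theta-band emotion-minus-neutral
#' PLV contrasts with the six regional group means/SDs of the reference
#' summary table; and behavioral contrasts (recall-quality delta, IOS
#' closeness) at the reported group effect sizes (d = 1.45 and 0.94).
#'
#' @param n_happy,n_sad Dyad counts per group.
#' @param roi_targets Data frame with columns `roi`, `happy_mean`, `happy_sd`,
#'   `sad_mean`, `sad_sd` giving the per-ROI delta-PLV distributions.
#' @param neutral_plv Mean/SD of the per-dyad, per-ROI neutral-condition PLV.
#' @param recall_happy,recall_sad Mean/SD of the recall-quality delta score.
#' @param ios_happy,ios_sad Mean/SD of the IOS closeness rating (1-7 scale).
#' @param band Band designator for the coupling.
#' @param carrier_hz Carrier frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param epochs Epochs per condition (default 240, i.e. a 4 min story at
#'   1000 ms epochs).
#' @param samples_per_epoch Phase samples per epoch (default 250).
#' @param channels_per_roi Coupled channels per ROI, `Inf` = all ROI channels.
#' @param rois ROI map.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_happy = 15, n_sad = 17,
                        roi_targets = default_roi_targets(),
                        neutral_plv = c(mean = 0.30, sd = 0.05),
                        recall_happy = c(mean = 8.0, sd = 3.5),
                        recall_sad = c(mean = 3.0, sd = 3.4),
                        ios_happy = c(mean = 5.4, sd = 1.1),
                        ios_sad = c(mean = 4.3, sd = 1.2),
                        band = "theta", carrier_hz = 5.5, fs = 250,
                        epochs = 240, samples_per_epoch = 250,
                        channels_per_roi = Inf, rois = default_roi_map(),
                        seed = 1) {
  stopifnot(n_happy > 0, n_sad > 0,
            all(c("roi", "happy_mean", "happy_sd", "sad_mean", "sad_sd")
                %in% names(roi_targets)),
            all(roi_targets$happy_sd > 0), all(roi_targets$sad_sd > 0),
            neutral_plv[["sd"]] > 0, recall_happy[["sd"]] > 0,
            recall_sad[["sd"]] > 0, ios_happy[["sd"]] > 0,
            ios_sad[["sd"]] > 0, epochs >= 1, samples_per_epoch >= 2)
  stopifnot(all(roi_targets$roi %in% names(rois)))
  structure(
    list(n_happy = n_happy, n_sad = n_sad, roi_targets = roi_targets,
         neutral_plv = neutral_plv, recall_happy = recall_happy,
         recall_sad = recall_sad, ios_happy = ios_happy, ios_sad = ios_sad,
         band = as_band(band), carrier_hz = carrier_hz, fs = fs,
         epochs = epochs, samples_per_epoch = samples_per_epoch,
         channels_per_roi = channels_per_roi, rois = rois, seed = seed),
    class = "cohort_spec"
  )
}

#' Default per-ROI delta-PLV group targets
#'
#' The six regional theta-band emotion-minus-neutral PLV means and SDs of the
#' reference two-group summary (happy n = 15 vs sad n = 17).
#'
#' @return Data frame with one row per ROI.
#' @export
default_roi_targets <- function() {
  data.frame(
    roi = c("F", "FC", "P", "right_tp", "left_tp", "O"),
    happy_mean = c(0.32, 0.47, 0.35, 0.01, 0.39, 0.02),
    happy_sd = c(0.10, 0.09, 0.09, 0.05, 0.10, 0.10),
    sad_mean = c(0.21, 0.45, 0.32, 0.00, 0.27, 0.01),
    sad_sd = c(0.09, 0.15, 0.11, 0.09, 0.08, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-group cohort
#'
#' For every dyad, each ROI receives a per-dyad neutral-condition PLV level
#' and a group-specific delta-PLV draw; the emotion-condition PLV is their
#' sum and both conditions are realized as von Mises phase-difference
#' coupling at the implied concentration. At `level = "phase"` (the fast
#' calibration surface) the generator emits exact phase series per condition;
#' at `level = "signal"` it emits waveform recordings (via
#' [make_coupled_dyad()]) plus a resting-state segment per participant.
#'
#' @param spec A [cohort_spec()].
#' @param level `"phase"` or `"signal"`.
#' @param rest_duration Resting segment length in seconds (signal level).
#' @param signal_duration Task recording length in seconds (signal level;
#'   default `spec$epochs` seconds, one epoch per second).
#' @return Object of class `ibs_cohort`: list with `dyads` (per dyad: group,
#'   condition name, per-condition data), `behavior` (data frame `dyad_id`,
#'   `group`, `recall_emotion`, `recall_neutral`, `delta_recall`, `ios`),
#'   `truth` (per-dyad per-ROI generated PLV levels) and `spec`.
#' @export
make_cohort <- function(spec, level = c("phase", "signal"),
                        rest_duration = 60, signal_duration = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  level <- match.arg(level)
  set.seed(spec$seed)
  n_total <- spec$n_happy + spec$n_sad
  groups <- rep(c("happy", "sad"), c(spec$n_happy, spec$n_sad))
  rt <- spec$roi_targets
  chans_per_roi <- lapply(rt$roi, function(r) {
    labs <- spec$rois[[r]]
    k <- min(length(labs), spec$channels_per_roi)
    labs[seq_len(k)]
  })
  names(chans_per_roi) <- rt$roi
  all_chans <- unlist(chans_per_roi, use.names = FALSE)

  dyads <- vector("list", n_total)
  truth <- list()
  beh <- data.frame()
  for (d in seq_len(n_total)) {
    g <- groups[d]
    id <- sprintf("dyad%02d", d)
    neu <- pmin(pmax(stats::rnorm(nrow(rt), spec$neutral_plv[["mean"]],
                                  spec$neutral_plv[["sd"]]), 0.05), 0.90)
    dl <- if (g == "happy") stats::rnorm(nrow(rt), rt$happy_mean, rt$happy_sd)
          else stats::rnorm(nrow(rt), rt$sad_mean, rt$sad_sd)
    emo <- pmin(pmax(neu + dl, 0.02), 0.98)
    truth[[d]] <- data.frame(dyad_id = id, group = g, roi = rt$roi,
                             plv_neutral = neu, plv_emotion = emo,
                             delta_plv = emo - neu, stringsAsFactors = FALSE)
    kap_emo <- kappa_from_plv(emo)
    kap_neu <- kappa_from_plv(neu)
    cond_emo <- g # "happy" or "sad"

    if (level == "phase") {
      gen_cond <- function(kaps, condition) {
        ph_s <- array(NA_real_, c(spec$epochs, length(all_chans),
                                  spec$samples_per_epoch))
        ph_l <- ph_s
        col <- 0
        tt <- (seq_len(spec$epochs * spec$samples_per_epoch) - 1) / spec$fs
        for (i in seq_along(rt$roi)) {
          for (ch in chans_per_roi[[i]]) {
            col <- col + 1
            theta <- 2 * pi * spec$carrier_hz * tt + stats::runif(1, 0, 2 * pi)
            delta <- rvonmises(length(tt), kaps[i])
            ph_s[, col, ] <- matrix(.wrap_pi(theta), spec$epochs,
                                    spec$samples_per_epoch, byrow = TRUE)
            ph_l[, col, ] <- matrix(.wrap_pi(theta - delta), spec$epochs,
                                    spec$samples_per_epoch, byrow = TRUE)
          }
        }
        list(
          speaker = phase_series(ph_s, spec$band, spec$fs, all_chans,
                                 "speaker", condition, id),
          listener = phase_series(ph_l, spec$band, spec$fs, all_chans,
                                  "listener", condition, id)
        )
      }
      dyads[[d]] <- list(dyad_id = id, group = g,
                         emotion = gen_cond(kap_emo, cond_emo),
                         neutral = gen_cond(kap_neu, "neutral"))
    } else {
      dur <- if (is.null(signal_duration)) spec$epochs else signal_duration
      mk <- function(kaps, condition) {
        cp <- lapply(seq_along(rt$roi), function(i) {
          coupling_spec(rt$roi[i], kaps[i], spec$band, spec$carrier_hz,
                        spec$rois)
        })
        make_coupled_dyad(cp, fs = spec$fs, duration = dur,
                          montage = c(all_chans, "M1", "M2"),
                          rois = spec$rois, dyad_id = id,
                          condition = condition)
      }
      rest <- function(role) {
        continuous_recording(
          t(replicate(length(all_chans) + 2,
                      .pink_noise(round(rest_duration * spec$fs), spec$fs, 20))),
          spec$fs, c(all_chans, "M1", "M2"), role, "rest", id)
      }
      dyads[[d]] <- list(dyad_id = id, group = g,
                         emotion = mk(kap_emo, cond_emo),
                         neutral = mk(kap_neu, "neutral"),
                         rest = list(speaker = rest("speaker"),
                                     listener = rest("listener")))
    }

    rq <- if (g == "happy") spec$recall_happy else spec$recall_sad
    io <- if (g == "happy") spec$ios_happy else spec$ios_sad
    delta_recall <- stats::rnorm(1, rq[["mean"]], rq[["sd"]])
    recall_neutral <- pmax(0, pmin(30, stats::rnorm(1, 15, 3)))
    ios <- pmax(1, pmin(7, stats::rnorm(1, io[["mean"]], io[["sd"]])))
    beh <- rbind(beh, data.frame(
      dyad_id = id, group = g,
      recall_emotion = recall_neutral + delta_recall,
      recall_neutral = recall_neutral,
      delta_recall = delta_recall, ios = ios, stringsAsFactors = FALSE))
  }
  structure(
    list(dyads = dyads, behavior = beh, truth = do.call(rbind, truth),
         spec = spec, level = level),
    class = "ibs_cohort"
  )
}

#' Dyad-level ROI summary table for a whole cohort
#'
#' Runs the PLV estimator on every dyad's emotion and neutral condition and
#' assembles the per-dyad, per-ROI summary joined with the behavioral table.
#' Phase-level cohorts feed the generated phase series straight into
#' [plv_matrix()]; signal-level cohorts first run [preprocess()] and
#' [extract_phase()] on each recording.
#'
#' @param cohort An `ibs_cohort`.
#' @param params Preprocessing parameters (signal level only).
#' @return Data frame: one row per dyad with `dyad_id`, `group`, per-ROI
#'   emotion/neutral mean PLV and `dplv_<roi>` contrasts, plus the
#'   behavioral columns.
#' @export
summarize_cohort <- function(cohort, params = preprocess_defaults()) {
  stopifnot(inherits(cohort, "ibs_cohort"))
  rois <- cohort$spec$rois
  rows <- lapply(cohort$dyads, function(dy) {
    if (cohort$level == "phase") {
      em <- plv_matrix(dy$emotion$speaker, dy$emotion$listener)
      ne <- plv_matrix(dy$neutral$speaker, dy$neutral$listener)
    } else {
      phases <- function(rec) extract_phase(preprocess(rec, params),
                                            cohort$spec$band)
      em <- plv_matrix(phases(dy$emotion$speaker), phases(dy$emotion$listener))
      ne <- plv_matrix(phases(dy$neutral$speaker), phases(dy$neutral$listener))
    }
    present <- names(rois)[vapply(names(rois), function(r) {
      length(intersect(rownames(em$values), rois[[r]])) > 0
    }, logical(1))]
    cbind(dyad_roi_summary(em, ne, rois[present]), group = dy$group,
          stringsAsFactors = FALSE)
  })
  merge(do.call(rbind, rows), cohort$behavior, by = c("dyad_id", "group"))
}

#' @export
print.ibs_cohort <- function(x, ...) {
  cat(sprintf("<ibs_cohort> %d happy + %d sad dyads, level=%s, seed=%d\n",
              x$spec$n_happy, x$spec$n_sad, x$level, x$spec$seed))
  invisible(x)
}
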