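#' Z-score a task signal against resting-state statistics
#'
#' @param task Numeric vector (task-period signal).
#' @param rest_mean,rest_sd Mean and SD of the resting-state baseline;
#'   `rest_sd > 0`.
#' @return `(task - rest_mean) / rest_sd`.
#' @export
zscore_to_baseline <- function(task, rest_mean, rest_sd) {
  if (!is.finite(rest_sd) || rest_sd <= 0) {
    stop("degenerate baseline: rest_sd must be positive", call. = FALSE)
  }
  (task - rest_mean) / rest_sd
}

# lagged design matrix: columns are lags 1..p of each column of X
.lag_design <- function(X, p) {
  X <- as.matrix(X)
  n <- nrow(X)
  t_idx <- (p + 1):n
  cols <- lapply(seq_len(p), function(l) X[t_idx - l, , drop = FALSE])
  list(y_idx = t_idx, Z = do.call(cbind, cols))
}

# OLS residual sum of squares per response column, with rank check
.ols_rss <- function(Z, Y) {
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1) {
    stop("degenerate input: rank-deficient regression (collinear signals)",
         call. = FALSE)
  }
  res <- qr.resid(qrz, Y)
  colSums(as.matrix(res)^2)
}

#' Select a vector-autoregression order by information criterion
#'
#' Fits a joint VAR over orders `1..max_order` on a common effective sample
#' (conditioning on the first `max_order` observations) and returns the order
#' minimizing AIC or BIC, computed from the log determinant of the residual
#' covariance.
#'
#' @param x Numeric matrix (samples x variables) or vector.
#' @param max_order Largest candidate order, `>= 1`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return List `order` (selected) and `criterion` (its IC value).
#' @export
select_order <- function(x, max_order, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(x)
  d <- ncol(X)
  n <- nrow(X)
  stopifnot(max_order >= 1)
  if (n < 10 * max_order * d + max_order + 2) {
    stop("insufficient samples for max_order ", max_order, call. = FALSE)
  }
  t_idx <- (max_order + 1):n
  t_eff <- length(t_idx)
  Y <- X[t_idx, , drop = FALSE]
  ics <- vapply(seq_len(max_order), function(p) {
    cols <- lapply(seq_len(p), function(l) X[t_idx - l, , drop = FALSE])
    Z <- do.call(cbind, cols)
    qrz <- qr(cbind(1, Z))
    res <- as.matrix(qr.resid(qrz, Y))
    sigma <- crossprod(res) / t_eff
    ld <- determinant(sigma, logarithm = TRUE)$modulus
    k <- p * d^2
    ld + switch(criterion, AIC = 2 * k / t_eff, BIC = log(t_eff) * k / t_eff)
  }, numeric(1))
  best <- which.min(ics)
  list(order = best, criterion = ics[best])
}

#' Pairwise time-domain Granger causality
#'
#' For each direction, fits by least squares a full model (target on its own
#' lags plus the source's lags) and a reduced model (own lags only); the
#' Granger statistic is the log ratio of reduced to full residual variance,
#' `F = ln(RSS_reduced / RSS_full)` (nats, `>= 0` up to numerical
#' tolerance). Signals are demeaned before fitting.
#'
#' @param x,y Numeric vectors of equal length `>= 20 * order`.
#' @param order VAR lag order.
#' @return Object of class `gc_result`: `f_forward` (x -> y), `f_backward`
#'   (y -> x), `order`.
#' @export
pairwise_gc <- function(x, y, order) {
  stopifnot(length(x) == length(y), order >= 1)
  if (length(x) < 20 * order) {
    stop("signals too short for order ", order, call. = FALSE)
  }
  x <- x - mean(x)
  y <- y - mean(y)
  X <- cbind(x, y)
  lag_full <- .lag_design(X, order)
  lag_x <- .lag_design(matrix(x), order)
  lag_y <- .lag_design(matrix(y), order)
  t_idx <- lag_full$y_idx
  rss_full <- .ols_rss(lag_full$Z, cbind(x[t_idx], y[t_idx]))
  rss_red_y <- .ols_rss(lag_y$Z, matrix(y[t_idx]))
  rss_red_x <- .ols_rss(lag_x$Z, matrix(x[t_idx]))
  structure(
    list(f_forward = log(rss_red_y / rss_full[2]),
         f_backward = log(rss_red_x / rss_full[1]),
         order = order),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> order=%d: F(forward)=%.4f F(backward)=%.4f\n",
              x$order, x$f_forward, x$f_backward))
  invisible(x)
}

#' Directional coupling of one dyad with baseline normalization
#'
#' Z-scores the speaker and listener task signals against their own
#' resting-state mean/SD, selects the VAR order by information criterion and
#' returns the pairwise Granger statistics speaker -> listener (`f_forward`)
#' and listener -> speaker (`f_backward`).
#'
#' @param speaker,listener Task-period ROI signals (numeric vectors, equal
#'   length).
#' @param speaker_rest,listener_rest Resting-state segments providing the
#'   baseline mean/SD for each participant.
#' @param max_order Largest candidate VAR order (default 20).
#' @param criterion `"AIC"` or `"BIC"`.
#' @return A `gc_result` with the selected `order` and its `criterion` value.
#' @export
dyad_gc <- function(speaker, listener, speaker_rest, listener_rest,
                    max_order = 20, criterion = "AIC") {
  zs <- zscore_to_baseline(speaker, mean(speaker_rest), stats::sd(speaker_rest))
  zl <- zscore_to_baseline(listener, mean(listener_rest), stats::sd(listener_rest))
  sel <- select_order(cbind(zs, zl), max_order, criterion)
  out <- pairwise_gc(zs, zl, sel$order)
  out$criterion <- sel$criterion
  out
}

#' ROI-mean time series from a continuous recording
#'
#' Average of all channels of a recording that belong to the named ROI —
#' the default input signal for directional coupling analysis.
#'
#' @param rec A `continuous_recording`.
#' @param roi ROI name (default `"F"`, frontal).
#' @param rois ROI map.
#' @return Numeric vector.
#' @export
roi_signal <- function(rec, roi = "F", rois = default_roi_map()) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (!roi %in% names(rois)) stop("unknown ROI: ", roi, call. = FALSE)
  chans <- intersect(rec$labels, rois[[roi]])
  if (!length(chans)) stop("no channels of ROI ", roi, " in recording",
                           call. = FALSE)
  colMeans(rec$data[chans, , drop = FALSE])
}
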