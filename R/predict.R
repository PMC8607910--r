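#' Configuration for closeness prediction by epsilon-SVR
#'
#' Defaults follow the published protocol: epsilon-insensitive support-vector
#' regression with an RBF kernel, `epsilon = 0.01`, a random 70/30
#' train/test split, `(C, gamma)` grid search by five-fold cross-validation
#' on the training set only, and 10,000 label permutations for significance.
#' The grid spans `C` in `2^-5 .. 2^15` and `gamma` in `2^-15 .. 2^3` in
#' powers of 4.
#'
#' @param epsilon SVR tube width.
#' @param c_grid,gamma_grid Hyperparameter grids.
#' @param train_fraction Training proportion, in (0, 1).
#' @param cv_folds Cross-validation folds, `>= 2`.
#' @param n_permutations Label permutations, `>= 1`.
#' @param scale_features Standardize features using training-set statistics.
#' @param seed Integer seed controlling split, folds and permutations.
#' @return Object of class `prediction_config`.
#' @export
prediction_config <- function(epsilon = 0.01,
                              c_grid = 2^seq(-5, 15, by = 2),
                              gamma_grid = 2^seq(-15, 3, by = 2),
                              train_fraction = 0.70, cv_folds = 5,
                              n_permutations = 10000,
                              scale_features = TRUE, seed = 1) {
  stopifnot(epsilon > 0, train_fraction > 0, train_fraction < 1,
            cv_folds >= 2, n_permutations >= 1,
            length(c_grid) >= 1, length(gamma_grid) >= 1)
  structure(
    list(epsilon = epsilon, c_grid = c_grid, gamma_grid = gamma_grid,
         train_fraction = train_fraction, cv_folds = cv_folds,
         n_permutations = n_permutations, scale_features = scale_features,
         seed = seed),
    class = "prediction_config"
  )
}

#' Build a dyad x electrode-pair feature table from PLV matrices
#'
#' One row per dyad; one column per (speaker channel, listener channel)
#' pair, ordered deterministically by speaker label then listener label.
#' When neutral-condition matrices are supplied the features are
#' emotion-minus-neutral PLV contrasts; otherwise raw PLV.
#'
#' @param plv_emotion Named list of `plv_matrix` objects (one per dyad).
#' @param plv_neutral Optional matching list for the neutral condition.
#' @return Numeric matrix, dyads x pairs, with dyad ids as row names and
#'   `"<speaker>|<listener>"` column names.
#' @export
build_features <- function(plv_emotion, plv_neutral = NULL) {
  stopifnot(length(plv_emotion) >= 1)
  ref <- plv_emotion[[1]]$values
  sp <- sort(rownames(ref))
  li <- sort(colnames(ref))
  pair_names <- as.vector(outer(li, sp, function(l, s) paste0(s, "|", l)))
  rows <- lapply(seq_along(plv_emotion), function(i) {
    v <- plv_emotion[[i]]$values
    if (!identical(sort(rownames(v)), sp) || !identical(sort(colnames(v)), li)) {
      stop("inconsistent montage across dyads", call. = FALSE)
    }
    m <- v[sp, li, drop = FALSE]
    if (!is.null(plv_neutral)) {
      nv <- plv_neutral[[i]]$values
      if (!identical(sort(rownames(nv)), sp) || !identical(sort(colnames(nv)), li)) {
        stop("inconsistent montage across dyads", call. = FALSE)
      }
      m <- m - nv[sp, li, drop = FALSE]
    }
    as.vector(t(m)) # speaker-major: all listener pairs of speaker 1 first
  })
  out <- do.call(rbind, rows)
  colnames(out) <- pair_names
  rownames(out) <- vapply(plv_emotion, function(p) p$dyad_id, character(1))
  out
}

# deterministic stratified split: indices of training rows
.stratified_split <- function(n, groups, frac) {
  if (is.null(groups)) groups <- rep("all", n)
  train <- integer(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    k <- max(1, min(length(idx) - 1, round(length(idx) * frac)))
    train <- c(train, sort(sample(idx, k)))
  }
  sort(train)
}

.fit_svr <- function(X, y, cost, gamma, epsilon) {
  e1071::svm(X, y, type = "eps-regression", kernel = "radial",
             cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

# grid search by k-fold CV mean squared error on training rows only
.grid_search <- function(X, y, config) {
  n <- nrow(X)
  folds <- sample(rep_len(seq_len(config$cv_folds), n))
  grid <- expand.grid(cost = config$c_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 1) return(list(cost = grid$cost[1], gamma = grid$gamma[1]))
  mse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
      m <- .fit_svr(X[tr, , drop = FALSE], y[tr], grid$cost[i],
                    grid$gamma[i], config$epsilon)
      mean((stats::predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(mse) # ties resolve to the first grid point
  list(cost = grid$cost[best], gamma = grid$gamma[best])
}

#' Train epsilon-SVR on a random split and score held-out prediction accuracy
#'
#' Draws a seed-deterministic stratified 70/30 split, selects `(C, gamma)` by
#' k-fold cross-validation on the training rows only, refits on the full
#' training set and reports the Pearson correlation between actual and
#' predicted closeness on the held-out rows. Feature standardization, when
#' enabled, is fit on training rows and applied to test rows.
#'
#' @param features Numeric matrix, dyads x features.
#' @param labels Numeric response (closeness ratings).
#' @param config A [prediction_config()].
#' @param groups Optional stratification labels for the split.
#' @return List of class `svr_prediction`: `predicted`, `actual`, `r`,
#'   `cost`, `gamma`, `train_idx`, `test_idx`.
#' @export
fit_predict <- function(features, labels, config = prediction_config(),
                        groups = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (stats::sd(labels) == 0) {
    stop("degenerate labels: response is constant", call. = FALSE)
  }
  if (n < config$cv_folds + 2) {
    stop("need at least cv_folds + 2 rows", call. = FALSE)
  }
  set.seed(config$seed)
  res <- .fit_predict_presplit(features, labels, config, groups)
  class(res) <- "svr_prediction"
  res
}

# core pipeline using the current RNG stream (no reseeding); callers that
# need determinism seed before calling
.fit_predict_presplit <- function(features, labels, config, groups) {
  n <- nrow(features)
  train <- .stratified_split(n, groups, config$train_fraction)
  test <- setdiff(seq_len(n), train)
  Xtr <- features[train, , drop = FALSE]
  Xte <- features[test, , drop = FALSE]
  if (config$scale_features) {
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, stats::sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
  }
  hp <- .grid_search(Xtr, labels[train], config)
  model <- .fit_svr(Xtr, labels[train], hp$cost, hp$gamma, config$epsilon)
  pred <- stats::predict(model, Xte)
  r <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, labels[test])
  list(predicted = unname(pred), actual = labels[test], r = r,
       cost = hp$cost, gamma = hp$gamma, train_idx = train, test_idx = test)
}

#' @export
print.svr_prediction <- function(x, ...) {
  cat(sprintf("<svr_prediction> r = %.3f on %d held-out dyads (C = %g, gamma = %g)\n",
              x$r, length(x$actual), x$cost, x$gamma))
  invisible(x)
}

#' Permutation significance of the SVR prediction accuracy
#'
#' Re-runs the entire split / cross-validated grid search / fit pipeline
#' under `n_permutations` random relabelings (labels shuffled across the
#' whole cohort before splitting, a fresh split each time) and compares the
#' observed held-out `r` one-sidedly against the permuted values with the
#' add-one correction: `p = (1 + #(r_perm >= r_obs)) / (1 + B)`; the p value
#' is therefore never exactly 0.
#'
#' @param features,labels,config,groups As in [fit_predict()].
#' @return List: `p_perm`, `r_obs`, `r_perm` (vector), `observed` (the
#'   `svr_prediction`).
#' @export
permutation_test <- function(features, labels, config = prediction_config(),
                             groups = NULL) {
  observed <- fit_predict(features, labels, config, groups)
  B <- config$n_permutations
  r_perm <- numeric(B)
  set.seed(config$seed + 1L)
  for (b in seq_len(B)) {
    yb <- sample(labels)
    r_perm[b] <- .fit_predict_presplit(features, yb, config, groups)$r
  }
  p <- (1 + sum(r_perm >= observed$r)) / (1 + B)
  list(p_perm = p, r_obs = observed$r, r_perm = r_perm, observed = observed)
}
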