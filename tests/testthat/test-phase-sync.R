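test_that("plv_pair satisfies its analytic identities", {
  set.seed(1)
  phi <- runif(50, -pi, pi)
  expect_equal(plv_pair(phi, phi), 1)
  expect_equal(plv_pair(phi + 1.3, phi), 1) # constant offset
  # four symmetric phase differences cancel exactly
  expect_equal(plv_pair(c(0, pi / 2, pi, 3 * pi / 2), c(0, 0, 0, 0)), 0,
               tolerance = 1e-12)
  # two-point case: |(1 + i)/2| = sqrt(2)/2
  expect_equal(plv_pair(c(0, pi / 2), c(0, 0)), sqrt(2) / 2, tolerance = 1e-12)
  # symmetry
  a <- runif(30, -pi, pi); b <- runif(30, -pi, pi)
  expect_equal(plv_pair(a, b), plv_pair(b, a))
  expect_error(plv_pair(a, b[1:10]), "equal length")
})

test_that("extracted phase of a pure tone advances at the carrier frequency", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  rec <- continuous_recording(matrix(sin(2 * pi * 5.5 * t), 1), fs, "Fz",
                              "speaker", "neutral")
  ps <- extract_phase(epoch_recording(rec, 1000), "theta")
  incs <- unlist(lapply(1:10, function(e) diff(ps$phases[e, 1, ps$valid])))
  incs <- ((incs + pi) %% (2 * pi)) - pi
  slope <- median(incs) * fs
  expect_lt(abs(slope - 2 * pi * 5.5) / (2 * pi * 5.5), 0.01)
})

test_that("a known phase offset between channels is recovered", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  d <- rbind(sin(2 * pi * 5.5 * t), sin(2 * pi * 5.5 * t - pi / 3))
  rec <- continuous_recording(d, fs, c("Fz", "Cz"), "speaker", "neutral")
  ps <- extract_phase(epoch_recording(rec, 1000), "theta")
  diffs <- ps$phases[, 1, ps$valid] - ps$phases[, 2, ps$valid]
  mean_diff <- Arg(mean(exp(1i * diffs)))
  expect_lt(abs(mean_diff - pi / 3), 0.05)
})

test_that("degenerate and empty inputs raise the documented errors", {
  fs <- 250
  rec <- continuous_recording(matrix(0, 1, fs * 4), fs, "Fz", "speaker", "neutral")
  ep <- epoch_recording(rec, 1000)
  expect_error(extract_phase(ep, "theta"), "degenerate")
  rec2 <- continuous_recording(matrix(rnorm(fs * 4), 1), fs, "Fz", "speaker",
                               "neutral")
  ep2 <- epoch_recording(rec2, 1000)
  ep2$retained[] <- FALSE
  expect_error(extract_phase(ep2, "theta"), "empty after rejection")
})

test_that("plv_matrix equals the brute-force triple loop on small instances", {
  set.seed(7)
  for (trial in 1:3) {
    sp <- array(runif(5 * 4 * 12, -pi, pi), c(5, 4, 12))
    lp <- array(runif(5 * 3 * 12, -pi, pi), c(5, 3, 12))
    s <- phase_series(sp, "theta", 250, paste0("s", 1:4))
    l <- phase_series(lp, "theta", 250, paste0("l", 1:3))
    s$retained[2] <- FALSE
    m <- plv_matrix(s, l)
    expect_equal(unname(m$values),
                 brute_plv_matrix(sp, lp, s$retained, s$valid & l$valid),
                 tolerance = 1e-12)
  }
})

test_that("self-pairing gives a unit diagonal", {
  set.seed(8)
  ph <- array(runif(4 * 3 * 20, -pi, pi), c(4, 3, 20))
  s <- phase_series(ph, "theta", 250, c("Fz", "Cz", "Pz"))
  m <- plv_matrix(s, s)
  expect_equal(unname(diag(m$values)), rep(1, 3))
})

test_that("independent uniform phases match the Monte-Carlo null mean", {
  set.seed(9)
  n <- 250
  sp <- array(runif(100 * 3 * n, -pi, pi), c(100, 3, n))
  lp <- array(runif(100 * 3 * n, -pi, pi), c(100, 3, n))
  m <- plv_matrix(phase_series(sp, "theta", 250, paste0("s", 1:3)),
                  phase_series(lp, "theta", 250, paste0("l", 1:3)))
  null_mean <- mc_null_plv_mean(n, 4000)
  expect_lt(abs(mean(m$values) - null_mean), 0.01)
  # asymptotic form sqrt(pi)/(2 sqrt(N)) agrees with the oracle
  expect_lt(abs(null_mean - sqrt(pi) / (2 * sqrt(n))), 0.005)
})

test_that("epoch counts are equalized by truncation and joint retention", {
  set.seed(10)
  sp <- array(runif(6 * 2 * 10, -pi, pi), c(6, 2, 10))
  lp <- array(runif(4 * 2 * 10, -pi, pi), c(4, 2, 10))
  s <- phase_series(sp, "theta", 250, c("a", "b"))
  l <- phase_series(lp, "theta", 250, c("c", "d"))
  expect_silent(m <- plv_matrix(s, l))
  l2 <- l
  l2$retained[] <- FALSE
  expect_error(plv_matrix(s, l2), "empty after rejection")
  expect_error(plv_matrix(s, phase_series(lp, "alpha", 250, c("c", "d"))),
               "band")
})

test_that("across-epoch averaging mode matches its own brute force", {
  set.seed(12)
  sp <- array(runif(30 * 2 * 6, -pi, pi), c(30, 2, 6))
  lp <- array(runif(30 * 2 * 6, -pi, pi), c(30, 2, 6))
  s <- phase_series(sp, "theta", 250, c("a", "b"))
  l <- phase_series(lp, "theta", 250, c("c", "d"))
  m <- plv_matrix(s, l, mode = "across_epoch")
  brute <- matrix(0, 2, 2)
  for (i in 1:2) for (k in 1:2) {
    v <- vapply(1:6, function(t) Mod(mean(exp(1i * (sp[, i, t] - lp[, k, t])))),
                numeric(1))
    brute[i, k] <- mean(v)
  }
  expect_equal(unname(m$values), brute, tolerance = 1e-12)
})

test_that("ROI means average exactly the in-ROI pair block", {
  rois <- default_roi_map()
  labs <- c(rois$F[1:3], rois$O[1:2])
  vals <- matrix(runif(25), 5, 5, dimnames = list(labs, labs))
  m <- structure(list(values = vals, band = as_band("theta"),
                      dyad_id = "d", condition = "happy"),
                 class = "plv_matrix")
  expect_equal(roi_mean_plv(m, "F", rois), mean(vals[1:3, 1:3]))
  expect_equal(roi_mean_plv(m, "O", rois), mean(vals[4:5, 4:5]))
  ones <- m; ones$values[] <- 1
  expect_equal(roi_mean_plv(ones, "F", rois), 1)
  blk <- m; blk$values[] <- 0; blk$values[1:3, 1:3] <- 0.5
  expect_equal(roi_mean_plv(blk, "F", rois), 0.5)
  expect_equal(roi_mean_plv(m, "F", rois, homologous_only = TRUE),
               mean(diag(vals[1:3, 1:3])))
  expect_error(roi_mean_plv(m, "nose", rois), "unknown ROI")
})

test_that("delta contrasts subtract neutral from emotion", {
  expect_equal(delta_plv(0.5, 0.5), 0)
  expect_equal(delta_plv(0.7, 0.2), 0.5)
  expect_equal(delta_plv(0.2, 0.7), -0.5)
  expect_error(delta_plv(1.2, 0.5))
})

test_that("signal-path PLV is monotone in the coupling concentration", {
  kappas <- c(0, 0.5, 1, 2, 4)
  mont <- c("Fz", "M1", "M2")
  means <- vapply(kappas, function(k) {
    mean(vapply(1:30, function(s) {
      d <- make_coupled_dyad(coupling_spec("F", k), fs = 250, duration = 16,
                             montage = mont, noise_sd = 10, osc_amp = 20,
                             seed = 7000 + 31 * s)
      pp <- function(r) extract_phase(
        epoch_recording(bandpass_filter(r, 1, 45), 1000), "theta")
      plv_matrix(pp(d$speaker), pp(d$listener))$values[1, 1]
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(means))
  expect_true(all(means >= 0 & means <= 1))
})
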