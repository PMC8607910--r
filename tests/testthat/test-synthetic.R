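test_that("the Bessel-ratio PLV map matches numerical integration and inverts", {
  for (k in c(0.3, 1, 2, 5, 20)) {
    expect_equal(plv_from_kappa(k), bessel_ratio_integral(k), tolerance = 1e-8)
  }
  expect_equal(plv_from_kappa(0), 0)
  r <- c(0.1, 0.3, 0.698, 0.95)
  expect_equal(plv_from_kappa(kappa_from_plv(r)), r, tolerance = 1e-7)
  expect_gt(plv_from_kappa(1e6), 0.999999)
})

test_that("von Mises draws have the right resultant length and symmetry", {
  set.seed(21)
  x <- rvonmises(40000, 2)
  expect_equal(Mod(mean(exp(1i * x))), plv_from_kappa(2), tolerance = 0.01)
  expect_lt(abs(Arg(mean(exp(1i * x)))), 0.02) # centered at zero
  u <- rvonmises(40000, 0)
  expect_lt(Mod(mean(exp(1i * u))), 0.02) # uniform when kappa = 0
  expect_true(all(x > -pi & x <= pi))
})

test_that("coupled dyads realize the specified population PLV", {
  mont <- c("Fz", "M1", "M2")
  # strong-coupling limit: phase difference nearly degenerate
  d_inf <- make_coupled_dyad(coupling_spec("F", 1e6), fs = 250, duration = 8,
                             montage = mont, seed = 1)
  ph <- dyad_true_phases(d_inf)
  expect_gt(plv_matrix(ph$speaker, ph$listener)$values[1, 1], 0.999)
  # kappa = 2: Bessel-ratio target ~0.698
  d2 <- make_coupled_dyad(coupling_spec("F", 2), fs = 250, duration = 60,
                          montage = mont, seed = 2)
  ph2 <- dyad_true_phases(d2)
  expect_equal(plv_matrix(ph2$speaker, ph2$listener)$values[1, 1],
               plv_from_kappa(2), tolerance = 0.02)
})

test_that("uncoupled channels carry noise and coupled ROIs carry the carrier", {
  d <- make_coupled_dyad(coupling_spec("F", 5, carrier_hz = 5.5), fs = 250,
                         duration = 8, montage = c("Fz", "Oz", "M1", "M2"),
                         seed = 3, noise_sd = 5, osc_amp = 20)
  tr <- attr(d, "truth")
  expect_true(all(is.na(tr$speaker["Oz", ])))
  expect_false(anyNA(tr$speaker["Fz", ]))
  expect_equal(fft_peak_hz(d$speaker$data["Fz", ], 250), 5.5, tolerance = 0.1)
})

test_that("generator rejects invalid configurations", {
  expect_error(coupling_spec("nose", 1), "unknown ROI")
  expect_error(coupling_spec("F", -1))
  expect_error(coupling_spec("F", 1, band = "theta", carrier_hz = 10),
               "outside band")
  expect_error(make_coupled_dyad(coupling_spec("F", 1), duration = 2),
               "at least 4 s")
  expect_error(make_var_dyad(5000, 1.2), "unstable")
  expect_error(make_var_dyad(50, 0.5), "at least")
})

test_that("generation is byte-identical under a repeated seed", {
  mont <- c("Fz", "F3", "M1", "M2")
  a <- make_coupled_dyad(coupling_spec("F", 2), fs = 250, duration = 6,
                         montage = mont, seed = 99)
  b <- make_coupled_dyad(coupling_spec("F", 2), fs = 250, duration = 6,
                         montage = mont, seed = 99)
  expect_identical(a$speaker$data, b$speaker$data)
  expect_identical(a$listener$data, b$listener$data)
  s1 <- make_cohort(tiny_cohort_spec(7))
  s2 <- make_cohort(tiny_cohort_spec(7))
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$dyads[[3]]$emotion$speaker$phases,
                   s2$dyads[[3]]$emotion$speaker$phases)
})

test_that("VAR dyads have the stated unidirectional structure", {
  vd <- make_var_dyad(10000, 0.5, 1, seed = 13)
  # y regressed on lagged x recovers the drive; x has no dependence on y
  fit <- lm(vd$y[-1] ~ vd$x[-10000])
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.05)
  g0 <- pairwise_gc(make_var_dyad(20000, 0, 1, seed = 14)$x,
                    make_var_dyad(20000, 0, 1, seed = 15)$y, 1)
  expect_lt(abs(g0$f_forward), 5e-4)
  expect_lt(abs(g0$f_backward), 5e-4)
})

test_that("cohort structure, behavior table and truth are coherent", {
  co <- make_cohort(tiny_cohort_spec(5))
  expect_length(co$dyads, 32)
  expect_equal(sum(co$behavior$group == "happy"), 15)
  expect_equal(sum(co$behavior$group == "sad"), 17)
  expect_named(co$behavior, c("dyad_id", "group", "recall_emotion",
                              "recall_neutral", "delta_recall", "ios"))
  expect_equal(co$behavior$delta_recall,
               with(co$behavior, recall_emotion - recall_neutral),
               tolerance = 1e-9)
  expect_true(all(co$behavior$ios >= 1 & co$behavior$ios <= 7))
  expect_equal(co$truth$delta_plv, co$truth$plv_emotion - co$truth$plv_neutral)
  expect_true(all(co$truth$plv_emotion > 0 & co$truth$plv_emotion < 1))
  # condition tags follow the group
  expect_equal(co$dyads[[1]]$emotion$speaker$condition, "happy")
  expect_equal(co$dyads[[32]]$emotion$speaker$condition, "sad")
})

test_that("identical coupling across groups yields a null group contrast", {
  rt <- default_roi_targets()[1, ]
  rt$sad_mean <- rt$happy_mean
  rt$sad_sd <- rt$happy_sd
  ps <- vapply(1:30, function(s) {
    co <- make_cohort(tiny_cohort_spec(400 + s, roi_targets = rt))
    sm <- summarize_cohort(co)
    independent_ttest(sm$dplv_F[sm$group == "happy"],
                      sm$dplv_F[sm$group == "sad"])$p
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.90)
})

test_that("signal-level cohorts produce recordings with resting segments", {
  rt <- default_roi_targets()[c(1, 5), ]
  spec <- cohort_spec(n_happy = 2, n_sad = 2, roi_targets = rt,
                      channels_per_roi = 1, epochs = 6, seed = 8)
  co <- make_cohort(spec, level = "signal", rest_duration = 5,
                    signal_duration = 6)
  dy <- co$dyads[[1]]
  expect_s3_class(dy$emotion$speaker, "continuous_recording")
  expect_equal(dy$rest$listener$condition, "rest")
  expect_equal(ncol(dy$rest$speaker$data), 5 * 250)
  expect_true(all(c("M1", "M2") %in% dy$emotion$speaker$labels))
})
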