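make_rec <- function(data, fs = 1000, labels = NULL) {
  data <- if (is.matrix(data)) data else matrix(data, nrow = 1)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  continuous_recording(data, fs, labels, "speaker", "neutral", "d01")
}

test_that("band-pass keeps in-band tones and suppresses out-of-band tones", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  s60 <- make_rec(sin(2 * pi * 60 * t), fs)
  out60 <- bandpass_filter(s60, 1, 45)
  expect_lt(rms(out60$data), 0.10 * rms(s60$data))
  s10 <- make_rec(sin(2 * pi * 10 * t), fs)
  out10 <- bandpass_filter(s10, 1, 45)
  expect_lt(abs(rms(out10$data) - rms(s10$data)) / rms(s10$data), 0.05)
  expect_error(bandpass_filter(s10, 1, 600), "Nyquist")
})

test_that("narrow band-pass centers white-noise power inside the band", {
  set.seed(11)
  rec <- make_rec(rnorm(20000), 1000)
  out <- bandpass_filter(rec, 4, 7)
  cen <- spectral_centroid_hz(out$data[1, ], 1000)
  expect_gte(cen, 4)
  expect_lte(cen, 7)
})

test_that("notch suppresses the notch frequency only", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  s50 <- make_rec(sin(2 * pi * 50 * t), fs)
  expect_lt(rms(notch_filter(s50, 50)$data), rms(s50$data) / 10)
  s40 <- make_rec(sin(2 * pi * 40 * t), fs)
  expect_lt(abs(rms(notch_filter(s40, 50)$data) - rms(s40$data)) / rms(s40$data),
            0.10)
  mixed <- make_rec(sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t), fs)
  out <- notch_filter(mixed, 50)$data[1, ]
  n <- length(out)
  sp <- Mod(fft(out))^2
  bin <- function(f) round(f * n / fs) + 1
  expect_gt(sp[bin(10)], 100 * sp[bin(50)])
})

test_that("mastoid re-referencing subtracts the mastoid average and drops mastoids", {
  set.seed(2)
  d <- rbind(rnorm(100), rnorm(100), rnorm(100), rnorm(100))
  rec <- make_rec(d, 250, c("Fz", "Cz", "M1", "M2"))
  # zero mastoids: scalp unchanged
  rec0 <- make_rec(rbind(d[1:2, ], 0, 0), 250, c("Fz", "Cz", "M1", "M2"))
  out0 <- rereference_mastoids(rec0)
  expect_equal(out0$data, rec0$data[1:2, ], ignore_attr = TRUE)
  expect_identical(out0$labels, c("Fz", "Cz"))
  # mastoids equal to a channel: that channel goes to zero
  recc <- make_rec(rbind(d[1, ], d[2, ], d[1, ], d[1, ]), 250,
                   c("Fz", "Cz", "M1", "M2"))
  outc <- rereference_mastoids(recc)
  expect_equal(max(abs(outc$data["Fz", ])), 0)
  # random data: equals brute-force subtraction
  out <- rereference_mastoids(rec)
  ref <- (d[3, ] + d[4, ]) / 2
  expect_equal(out$data["Cz", ], d[2, ] - ref, ignore_attr = TRUE)
  expect_error(rereference_mastoids(make_rec(d[1:2, ], 250, c("Fz", "Cz"))),
               "M1")
})

test_that("downsampling preserves in-band content and sample arithmetic", {
  fs <- 1000
  t <- (0:(60 * fs - 1)) / fs
  rec <- make_rec(sin(2 * pi * 10 * t), fs)
  out <- downsample(rec, 250)
  expect_equal(ncol(out$data), 15000)
  expect_equal(out$fs, 250)
  expect_equal(fft_peak_hz(out$data[1, ], 250), 10, tolerance = 0.02)
  # constant stays constant
  cst <- downsample(make_rec(rep(3.5, 4000), fs), 250)
  expect_equal(cst$data[1, ], rep(3.5, 1000), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(downsample(rec, 2000), "below fs")
})

test_that("epoching cuts consecutive non-overlapping windows and drops the tail", {
  fs <- 250
  rec <- make_rec(matrix(seq_len(2 * 2625), 2), fs) # 10.5 s, 2 channels
  ep <- epoch_recording(rec, 1000)
  expect_equal(dim(ep$data), c(10, 2, 250))
  expect_true(all(ep$retained))
  # partition property: concatenation reproduces the first 10 s
  flat <- do.call(cbind, lapply(1:10, function(e) ep$data[e, , ]))
  expect_equal(flat, rec$data[, 1:2500], ignore_attr = TRUE)
  expect_equal(dim(epoch_recording(make_rec(rnorm(250), fs), 1000)$data)[1], 1)
  expect_error(epoch_recording(make_rec(rnorm(100), fs), 1000), "shorter")
})

test_that("amplitude rejection flags exactly the epochs with excursions", {
  fs <- 250
  d <- matrix(0, 2, 250 * 8)
  d[2, 3 * 250 + 17] <- 100 # one 100 uV spike in epoch 4
  ep <- epoch_recording(make_rec(d, fs), 1000)
  rej <- reject_amplitude(ep, 75)
  expect_identical(rej$retained, c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 4)))
  expect_identical(rej$data, ep$data) # data untouched
  expect_true(all(reject_amplitude(epoch_recording(make_rec(matrix(0, 2, 2000), fs), 1000), 75)$retained))
})

test_that("rejection fraction of Gaussian noise matches the normal closed form", {
  # 4 channels x 50 samples per epoch, SD 30, threshold 75 = 2.5 SD:
  # retain probability (2*Phi(2.5) - 1)^200
  set.seed(33)
  fs <- 50
  n_ep <- 1500
  d <- matrix(rnorm(4 * fs * n_ep, sd = 30), 4)
  ep <- epoch_recording(make_rec(d, fs, paste0("c", 1:4)), 1000)
  rej <- reject_amplitude(ep, 75)
  expected <- 1 - (2 * pnorm(2.5) - 1)^(4 * fs)
  observed <- mean(!rej$retained)
  se <- sqrt(expected * (1 - expected) / n_ep)
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("re-referencing commutes with linear-phase filtering", {
  set.seed(4)
  rec <- make_rec(matrix(rnorm(4 * 4000), 4), 1000, c("Fz", "Cz", "M1", "M2"))
  a <- rereference_mastoids(bandpass_filter(rec, 1, 45))
  b <- bandpass_filter(rereference_mastoids(rec), 1, 45)
  expect_equal(a$data, b$data, tolerance = 1e-4)
})

test_that("preprocessing operations leave their input unchanged", {
  set.seed(5)
  rec <- make_rec(matrix(rnorm(3 * 4000), 3), 1000, c("Fz", "M1", "M2"))
  snapshot <- rec$data + 0
  invisible(bandpass_filter(rec, 1, 45))
  invisible(notch_filter(rec, 50))
  invisible(rereference_mastoids(rec))
  invisible(downsample(rec, 250))
  expect_identical(rec$data, snapshot)
})

test_that("the full chain runs in the documented order and rejects artifacts", {
  set.seed(6)
  d <- make_coupled_dyad(coupling_spec("F", 3), fs = 250, duration = 12,
                         montage = c("Fz", "F3", "M1", "M2"),
                         artifact_fraction = 0.3, seed = 6)
  ep <- preprocess(d$listener, list(target_fs = 250))
  expect_s3_class(ep, "epoched_recording")
  expect_equal(dim(ep$data)[3], 250)
  expect_lt(sum(ep$retained), dim(ep$data)[1]) # some epochs rejected
  expect_false("M1" %in% ep$labels)
})
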