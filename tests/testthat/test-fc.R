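test_that("ROI extraction takes unweighted voxel means", {
  x <- matrix(0, 27, 20)
  x[1, ] <- sin(1:20)
  x[2, ] <- sin(1:20); x[3, ] <- -sin(1:20)
  x[4, ] <- 1; x[5, ] <- 2; x[6, ] <- 3
  sc <- scan4d(x, c(3, 3, 3), tr_s = 1)
  ts <- extract_roi_timeseries(sc, list(one = 1L, anti = 2:3, const = 4:6))
  expect_equal(ts$values["one", ], sin(1:20))
  expect_equal(ts$values["anti", ], rep(0, 20))
  expect_equal(ts$values["const", ], rep(2, 20))
  expect_error(extract_roi_timeseries(sc, list(integer(0))), "empty")
  expect_error(extract_roi_timeseries(sc, list(28L)), "outside")
})

test_that("band-pass gains match the Butterworth transfer-function oracle", {
  fs <- 10; T <- 4000; tt <- (0:(T - 1)) / fs
  core <- 500:3500  # avoid edge transients
  power_ratio <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- bandpass(roi_ts(x, tr_s = 1 / fs), 0.01, 0.1)$values[1, ]
    mean(y[core]^2) / mean(x[core]^2)
  }
  f_mid <- (0.01 + 0.1) / 2
  expect_gte(power_ratio(f_mid), 0.9)
  expect_lt(abs(power_ratio(f_mid) - filtfilt_gain(0.01, 0.1, fs, f_mid)),
            0.05)
  expect_lte(power_ratio(10 * 0.1), 0.01)
  expect_lt(abs(power_ratio(1) - filtfilt_gain(0.01, 0.1, fs, 1)), 0.01)
  # constant series: detrending removes DC entirely
  yc <- bandpass(roi_ts(rep(3.7, 200), tr_s = 1), 0.01, 0.2)$values[1, ]
  expect_lt(max(abs(yc)), 1e-8)
  expect_error(bandpass(roi_ts(rnorm(100), tr_s = 1), 0.01, 0.6), "Nyquist")
  expect_error(bandpass(roi_ts(rnorm(100), tr_s = 1), 0.2, 0.1), "low_hz")
})

test_that("the filter is nearly idempotent in its passband", {
  set.seed(14)
  x <- rnorm(2000)
  b1 <- bandpass(roi_ts(x, tr_s = 1), 0.01, 0.2)
  b2 <- bandpass(b1, 0.01, 0.2)
  core <- 200:1800
  p1 <- mean(b1$values[1, core]^2)
  p2 <- mean(b2$values[1, core]^2)
  expect_lt(abs(p2 - p1) / p1, 0.25)  # repeated filtering sharpens edges only
})

test_that("subject FC is Pearson with NA propagation for constant rows", {
  v <- rbind(rep(c(1, 2, 3, 4), 2), rep(c(1, 3, 2, 4), 2), rep(1, 8))
  ts <- structure(list(values = v, roi_ids = c("s", "t", "flat"), tr_s = 1),
                  class = "roi_timeseries")
  expect_warning(r <- subject_fc(ts, 1L, 2:3), "constant")
  expect_equal(unname(r[1, 1]), 0.8)
  expect_true(is.na(r[1, 2]))
  r_self <- subject_fc(ts, 1L, 1L)
  expect_equal(unname(r_self[1, 1]), 1)
  expect_error(subject_fc(structure(list(values = v[, 1:4], roi_ids = 1:3,
                                         tr_s = 1),
                                    class = "roi_timeseries"), 1L, 2L),
               ">= 8")
})

test_that("independent long series correlate within the sampling bound", {
  set.seed(15)
  v <- matrix(rnorm(2 * 4000), 2)
  ts <- structure(list(values = v, roi_ids = 1:2, tr_s = 1),
                  class = "roi_timeseries")
  expect_lte(abs(subject_fc(ts, 1L, 2L)[1, 1]), 0.05)
})

test_that("subject FC equals the double-loop Pearson oracle", {
  set.seed(16)
  v <- matrix(rnorm(7 * 60), 7)
  ts <- structure(list(values = v, roi_ids = 1:7, tr_s = 1),
                  class = "roi_timeseries")
  r <- subject_fc(ts, 1:3, 4:7)
  expect_lt(max(abs(r - naive_pearson(t(v[1:3, ]), t(v[4:7, ])))), 1e-10)
})

test_that("group fingerprints average raw r with between-subject SEM", {
  m1 <- matrix(0.2, 1, 1); m2 <- matrix(0.4, 1, 1)
  fp <- group_fingerprint(list(m1, m2), seed_positions = 0.5)
  expect_equal(unname(fp$mean_r[1, 1]), 0.3)
  expect_equal(unname(fp$sem[1, 1]), sd(c(0.2, 0.4)) / sqrt(2))
  expect_equal(unname(fp$sem[1, 1]), 0.1, tolerance = 1e-12)

  single <- group_fingerprint(list(m1), seed_positions = 0.5)
  expect_equal(unname(single$mean_r[1, 1]), 0.2)
  expect_true(is.na(single$sem[1, 1]))

  same <- group_fingerprint(list(m1, m1, m1), seed_positions = 0.5)
  expect_equal(unname(same$sem[1, 1]), 0)

  # NA cells are dropped pairwise with per-cell n
  mna <- matrix(NA_real_, 1, 1)
  fp2 <- group_fingerprint(list(m1, m2, mna), seed_positions = 0.5)
  expect_equal(unname(fp2$mean_r[1, 1]), 0.3)
  expect_equal(unname(fp2$n[1, 1]), 2)
  expect_error(group_fingerprint(list(m1, matrix(0.1, 2, 1)), c(0.5)),
               "shape")
})

test_that("fisher-z averaging is available and differs from raw averaging", {
  m1 <- matrix(0.1, 1, 1); m2 <- matrix(0.9, 1, 1)
  raw <- group_fingerprint(list(m1, m2), 0.5)
  fz <- group_fingerprint(list(m1, m2), 0.5, fisher_z = TRUE)
  expect_equal(unname(fz$mean_r[1, 1]), tanh(mean(atanh(c(0.1, 0.9)))))
  expect_gt(fz$mean_r[1, 1], raw$mean_r[1, 1])
})
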