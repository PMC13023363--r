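test_that("recordings at 512 Hz pass through resampling unchanged", {
  rec <- noise_recording(fs = 512, ictal_s = 10, preictal_s = 2)
  expect_identical(resample_to_512(rec), rec)
})

test_that("resampling a sine matches the analytic 512 Hz sampling", {
  fs0 <- 1024
  t0 <- seq(0, 8 - 1 / fs0, by = 1 / fs0)
  x <- sin(2 * pi * 10 * t0)
  rec <- seizure_recording(rbind(x, x), fs0, onset_sample = 2048,
                           offset_sample = length(t0),
                           preictal_samples = 2047)
  out <- resample_to_512(rec)
  expect_equal(out$fs, 512)
  expect_equal(out$onset_sample, 1024)   # index scaling 2048 @1024 -> @512
  t1 <- seq(0, by = 1 / 512, length.out = ncol(out$signal))
  ref <- sin(2 * pi * 10 * t1)
  core <- 100:(length(ref) - 100)        # ignore filter edge transients
  expect_gt(cor(out$signal[1, core], ref[core]), 0.999)
})

test_that("upsampling is refused with advice", {
  rec <- noise_recording(fs = 256, ictal_s = 5, preictal_s = 1)
  expect_error(resample_to_512(rec), "upsampling unsupported")
})

test_that("band-pass removes DC, rejects 50 Hz, passes 10 Hz at unity", {
  fs <- 512
  n <- fs * 30
  t <- seq_len(n) / fs
  mk <- function(x) seizure_recording(matrix(x, 1), fs, onset_sample = 2,
                                      offset_sample = n,
                                      preictal_samples = 1)
  core <- (5 * fs):(25 * fs)             # avoid filtfilt edge transients

  dc <- filter_signal(mk(rep(1, n)))
  expect_lt(max(abs(dc$signal[1, core])), 1e-6)

  s50 <- filter_signal(mk(sin(2 * pi * 50 * t)))
  atten_db <- 20 * log10(sd(s50$signal[1, core]) / sd(sin(2 * pi * 50 * t)))
  expect_lt(atten_db, -40)

  s10 <- filter_signal(mk(sin(2 * pi * 10 * t)))
  gain <- sd(s10$signal[1, core]) / sd(sin(2 * pi * 10 * t[core]))
  expect_lt(abs(gain - 1), 0.01)

  expect_error(filter_signal(mk(c(NA, rep(0, n - 1)))), "non-finite")
})

test_that("filtering already band-limited noise is near-idempotent", {
  set.seed(5)
  n <- 22 * 512
  bl <- signal::butter(2, c(2, 40) / 256, "pass")   # well inside the passband
  sig <- rbind(signal::filtfilt(bl, rnorm(n)), signal::filtfilt(bl, rnorm(n)))
  rec <- seizure_recording(sig, 512, onset_sample = 2 * 512 + 1,
                           offset_sample = n, preictal_samples = 2 * 512)
  once <- filter_signal(rec)
  twice <- filter_signal(once)
  core <- (2 * 512):(20 * 512)
  rms1 <- sd(once$signal[1, core]); rms2 <- sd(twice$signal[1, core])
  expect_lt(abs(rms2 - rms1) / rms1, 0.01)
})

test_that("noisy-channel detection flags amplitude outliers subject-wide", {
  recs <- lapply(1:3, function(k) {
    r <- noise_recording(n_channels = 6, fs = 256, ictal_s = 5,
                         preictal_s = 40, seed = k)
    r$signal[4, ] <- r$signal[4, ] * 100
    r
  })
  rep_ <- detect_noisy_channels(recs)
  expect_true(rep_$excluded[4])
  expect_equal(rep_$reason[4], "auto")
  expect_false(any(rep_$excluded[-4]))
})

test_that("identical channels yield no flags; manual list is honored", {
  x <- matrix(rnorm(4 * 256 * 45), 1)[1, ]
  sig <- do.call(rbind, replicate(4, x, simplify = FALSE))
  rec <- seizure_recording(sig, 256, onset_sample = 40 * 256 + 1,
                           offset_sample = ncol(sig),
                           preictal_samples = 40 * 256)
  rep_ <- detect_noisy_channels(list(rec), manual_bad = "ch3")
  expect_equal(rep_$excluded, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(rep_$reason[3], "manual")
  expect_error(detect_noisy_channels(list(rec),
                                     manual_bad = paste0("ch", 1:4)),
               "all channels")
})

test_that("common-average reference removes the common signal", {
  a <- rnorm(1000)
  rec <- seizure_recording(rbind(a, -a), 256, onset_sample = 500,
                           offset_sample = 1000, preictal_samples = 499)
  out <- common_average_reference(rec)
  expect_equal(out$signal, rbind(a = a, `-a` = -a) * 1,
               ignore_attr = TRUE, tolerance = 1e-12)

  sig <- matrix(rnorm(3000), 3) + 5     # common offset
  rec2 <- seizure_recording(sig, 256, onset_sample = 500,
                            offset_sample = 1000, preictal_samples = 499)
  out2 <- common_average_reference(rec2)
  expect_lt(max(abs(colMeans(out2$signal))), 1e-9)

  # excluded channel is dropped before averaging
  q <- data.frame(channel = c("ch1", "ch2", "ch3"),
                  excluded = c(FALSE, FALSE, TRUE))
  out3 <- common_average_reference(rec2, q)
  expect_equal(nrow(out3$signal), 2)
  expect_equal(out3$signal[1, ],
               rec2$signal[1, ] - colMeans(rec2$signal[1:2, ]),
               ignore_attr = TRUE)
  expect_error(common_average_reference(
    seizure_recording(matrix(rnorm(100), 1), 256, 50, 100, preictal_samples = 49)),
    "fewer than 2")
})

test_that("lead-seizure rule drops seizures within 120 s of the last retained", {
  ann <- data.frame(subject = "s1",
                    onset_s = c(0, 140, 300),
                    offset_s = c(30, 170, 320))
  # gaps: 110 s (drop) ; 300-30=270 to A's offset (keep: B was dropped)
  out <- select_lead_seizures(ann)
  expect_equal(out$retained, c(TRUE, FALSE, TRUE))
  expect_equal(out$drop_reason[2], "non_lead")

  ann2 <- data.frame(subject = "s1", onset_s = c(0, 155),
                     offset_s = c(30, 180))   # 125 s gap
  expect_true(all(select_lead_seizures(ann2)$retained))

  # chain: gaps measured against the most recent retained offset
  ann3 <- data.frame(subject = "s1",
                     onset_s = c(0, 130, 145),
                     offset_s = c(30, 140, 150))
  out3 <- select_lead_seizures(ann3)
  expect_equal(out3$retained, c(TRUE, FALSE, FALSE))
})

test_that("flagged seizures are dropped with reasons and overlaps error", {
  ann <- data.frame(subject = "s1",
                    onset_s = c(0, 500, 1000),
                    offset_s = c(30, 530, 1030),
                    sleep_deprivation = c(FALSE, TRUE, FALSE),
                    stimulation = FALSE,
                    excluded_period = c(FALSE, FALSE, TRUE))
  out <- select_lead_seizures(ann)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE))
  expect_equal(out$drop_reason[2], "sleep_deprivation")
  expect_equal(out$drop_reason[3], "excluded_period")

  bad <- data.frame(subject = "s1", onset_s = c(0, 20), offset_s = c(30, 50))
  expect_error(select_lead_seizures(bad), "overlapping")
})

test_that("no two retained seizures are ever closer than 120 s", {
  set.seed(42)
  for (k in 1:10) {
    on <- sort(runif(15, 0, 3000))
    dur <- runif(15, 5, 60)
    for (i in 2:15) on[i] <- max(on[i], on[i - 1] + dur[i - 1] + 0.5)
    off <- on + dur
    out <- select_lead_seizures(data.frame(subject = "s", onset_s = on,
                                           offset_s = off))
    ret <- out[out$retained, ]
    if (nrow(ret) > 1)
      expect_true(all(ret$onset_s[-1] - ret$offset_s[-nrow(ret)] >= 120))
  }
})
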