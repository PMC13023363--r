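test_that("window grid yields floor((T - 5)/1) + 1 windows", {
  rec <- noise_recording(n_channels = 2, fs = 256, preictal_s = 120,
                         ictal_s = 60, seed = 1)
  cm <- data.frame(channel = c("ch1", "ch2"), region = c("A", "B"))
  ft <- band_power_features(rec, cm)
  expect_equal(ft$n_windows, floor((60 - 5) / 1) + 1)   # 56
  expect_equal(dim(ft$z), c(2, 6, 56))
})

test_that("statistically identical ictal and preictal periods give z near 0", {
  rec <- noise_recording(n_channels = 3, fs = 256, preictal_s = 120,
                         ictal_s = 40, seed = 2)
  cm <- data.frame(channel = paste0("ch", 1:3), region = c("A", "A", "B"))
  ft <- band_power_features(rec, cm)
  # per-window z is ~unit-normal when ictal == preictal in distribution, so
  # the distribution must be centred on zero
  expect_lt(abs(median(ft$z)), 0.2)
  expect_lt(abs(mean(ft$z)), 0.2)
})

test_that("a planted alpha gain shows up in the right region and band", {
  set.seed(3)
  fs <- 256
  n_pre <- 120 * fs; n_ict <- 30 * fs
  sig <- matrix(rnorm(2 * (n_pre + n_ict)), 2)
  tt <- seq_len(n_ict) / fs
  sig[1, n_pre + seq_len(n_ict)] <- sig[1, n_pre + seq_len(n_ict)] +
    10 * sin(2 * pi * 10 * tt)          # strong 10 Hz (alpha) component
  rec <- seizure_recording(sig, fs, onset_sample = n_pre + 1,
                           offset_sample = n_pre + n_ict,
                           preictal_samples = n_pre)
  cm <- data.frame(channel = c("ch1", "ch2"), region = c("A", "B"))
  ft <- band_power_features(rec, cm)
  zA <- apply(ft$z[1, , , drop = TRUE], 1, mean)
  expect_gt(zA[3], 3 * max(zA[-3]))
  expect_error(band_power_features(
    seizure_recording(sig, fs, onset_sample = 20 * fs,
                      offset_sample = n_pre + n_ict,
                      preictal_samples = 10 * fs), cm),
    "30 s")
})

test_that("zero preictal variance is reported with the offending pair", {
  fs <- 256
  sig <- matrix(0, 2, 160 * fs)
  sig[2, ] <- rnorm(160 * fs)
  rec <- seizure_recording(sig, fs, onset_sample = 120 * fs + 1,
                           offset_sample = 160 * fs,
                           preictal_samples = 120 * fs)
  cm <- data.frame(channel = c("ch1", "ch2"), region = c("A", "B"))
  expect_error(band_power_features(rec, cm), "pre-ictal sd is zero.*A")
})

fake_features <- function(z) {
  structure(list(z = z, regions = sprintf("r%d", seq_len(dim(z)[1])),
                 bands = rownames(band_edges()),
                 window_starts_s = seq_len(dim(z)[3]) - 1,
                 n_windows = dim(z)[3]),
            class = "region_band_features")
}

test_that("build_X stacks region-major/band-minor and indexes round-trip", {
  f1 <- fake_features(array(1, c(4, 6, 10)))
  f2 <- fake_features(array(2, c(4, 6, 20)))
  Xb <- build_X(list(f1, f2))
  expect_equal(dim(Xb$X), c(24, 30))
  expect_equal(Xb$index$seizure[17], 2)
  expect_equal(Xb$index$window[17], 7)
  expect_equal(Xb$row_labels[7], "r2.delta")   # row (2-1)*6 + 1

  # placement: region 3 / band 2 of seizure 1 lands in row (3-1)*6+2
  z <- array(0, c(4, 6, 3)); z[3, 2, ] <- 5
  Xb2 <- build_X(list(fake_features(z)))
  expect_equal(Xb2$X[(3 - 1) * 6 + 2, ], rep(5, 3), ignore_attr = TRUE)
  expect_equal(sum(Xb2$X), 5 * 3)

  expect_equal(sum(build_X(list(fake_features(array(0, c(2, 6, 4)))))$X), 0)
  f3 <- fake_features(array(1, c(3, 6, 5)))
  expect_error(build_X(list(f1, f3)), "region sets differ")
})

test_that("negative handling clips at zero by default, shifts on request", {
  z <- array(-1, c(2, 6, 2)); z[1, 1, ] <- 2
  Xc <- build_X(list(fake_features(z)))$X
  expect_equal(min(Xc), 0)
  expect_equal(unname(Xc[1, 1]), 2)
  Xs <- build_X(list(fake_features(z)), negatives = "shift")$X
  expect_equal(min(Xs), 0)
  expect_equal(unname(Xs[1, 1]), 3)
})

test_that("NMF recovers planted factorizations", {
  set.seed(10)
  W0 <- matrix(runif(30), 10, 3); H0 <- matrix(runif(60), 3, 20)
  X <- W0 %*% H0
  m <- fit_nmf(X, 3, seed = 1)
  expect_lt(m$rel_error, 1e-3)
  expect_equal(apply(m$W, 2, max), rep(1, 3), tolerance = 1e-9)

  X1 <- outer(runif(10), runif(20))        # rank 1
  expect_lt(fit_nmf(X1, 1, seed = 1)$rel_error, 1e-6)

  m2 <- fit_nmf(X, 3, seed = 1)
  expect_identical(m$W, m2$W)              # determinism
  expect_identical(m$H, m2$H)
  expect_error(fit_nmf(X, 11, seed = 1), "rank bound")
  expect_error(fit_nmf(X - 10, 2), "X >= 0")
})

test_that("reconstruction error is non-increasing in nc", {
  cfg <- synthetic_config(n_subjects = 1, n_states_per_subject = 4,
                          regions_per_subject = 8, noise_sd = 0.3, seed = 9)
  Xb <- build_X(generate_cohort(cfg)$features[[1]])
  errs <- vapply(1:5, function(nc) fit_nmf(Xb$X, nc, seed = 1)$rel_error,
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("hard assignment follows argmax, threshold and tie rules", {
  mdl <- structure(list(H = cbind(c(0.9, 0.1, 0.2),
                                  c(0.1, 0.05, 0.2),
                                  c(0.5, 0.5, 0.1)),
                        W = diag(3), nc = 3),
                   class = "state_model")
  idx <- data.frame(col = 1:3, seizure = 1, window = 1:3)
  sq <- assign_states(mdl, idx, threshold = 0.3)
  expect_equal(sq$labels, c(1L, 0L, 1L))   # argmax / null / tie -> lowest
})

test_that("model order selection finds the planted number of states", {
  cfg <- synthetic_config(n_subjects = 1, n_states_per_subject = 3,
                          n_taper_emergent = 1, regions_per_subject = 9,
                          noise_sd = 0, seed = 2)
  Xb <- build_X(generate_cohort(cfg)$features[[1]])
  nc <- select_nc(Xb, 1:6, seed = 1)
  expect_equal(as.integer(nc), 3)

  X1 <- outer(runif(12), runif(40))
  Xb1 <- list(X = X1, index = data.frame(col = 1:40,
                                         seizure = rep(1:2, each = 20),
                                         window = rep(1:20, 2)))
  expect_equal(as.integer(select_nc(Xb1, 1:4, seed = 1)), 1)

  expect_message(nc5 <- select_nc(Xb, override = 5), "override")
  expect_equal(as.integer(nc5), 5)
  expect_true(attr(nc5, "override"))
  expect_error(select_nc(Xb, integer(0)), "empty candidate")
})

test_that("planted state sequences are recovered end to end", {
  # noiseless: exact; noise 0.5 z-units: >= 90% matched accuracy
  for (sd_ in 1:5) {
    for (ns in c(0, 0.5)) {
      cfg <- synthetic_config(n_subjects = 1, n_states_per_subject = 4,
                              regions_per_subject = 8, noise_sd = ns,
                              seed = sd_)
      co <- generate_cohort(cfg)
      Xb <- build_X(co$features[[1]])
      m <- fit_nmf(Xb$X, 4, seed = 1)
      sq <- assign_states(m, Xb$index, threshold = 0)
      gt <- co$ground_truth[[1]]
      rec <- relabel_states(unlist(sq$by_seizure), m$W, gt$W_true)
      acc <- mean(rec == unlist(gt$sequences))
      if (ns == 0) expect_equal(acc, 1) else expect_gte(acc, 0.9)
    }
  }
})

test_that("permuting region order permutes W rows and leaves labels alone", {
  cfg <- synthetic_config(n_subjects = 1, n_states_per_subject = 3,
                          regions_per_subject = 6, noise_sd = 0.2, seed = 4)
  co <- generate_cohort(cfg)
  feats <- co$features[[1]]
  perm <- c(4, 1, 6, 3, 2, 5)
  feats_p <- lapply(feats, function(f) {
    f$z <- f$z[perm, , , drop = FALSE]
    f$regions <- f$regions[perm]
    f
  })
  Xb <- build_X(feats)
  Xb_p <- build_X(feats_p)
  m <- fit_nmf(Xb$X, 3, seed = 1)
  m_p <- fit_nmf(Xb_p$X, 3, seed = 1)
  sq <- assign_states(m, Xb$index)
  sq_p <- assign_states(m_p, Xb_p$index)
  # row blocks of W follow the region permutation (after state matching)
  mt <- taperstates:::match_states(m_p$W, m$W)
  row_perm <- as.vector(t(outer((perm - 1) * 6, 1:6, "+")))
  expect_equal(m_p$W, m$W[row_perm, mt$perm],
               tolerance = 1e-6, ignore_attr = TRUE)
  # labels agree up to the same state relabelling
  lab <- sq$labels; lab_p <- sq_p$labels
  lab_pm <- lab_p
  lab_pm[lab_p > 0] <- mt$perm[lab_p[lab_p > 0]]
  expect_equal(lab_pm, lab)
})
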