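# shared fixture builders (all generated in code; nothing on disk)

# white-noise recording: n_channels x (preictal + ictal) at fs
noise_recording <- function(n_channels = 3, fs = 256, preictal_s = 120,
                            ictal_s = 60, seed = 1, sd = 1) {
  set.seed(seed)
  n <- round((preictal_s + ictal_s) * fs)
  n_pre <- round(preictal_s * fs)
  seizure_recording(matrix(rnorm(n_channels * n, 0, sd), n_channels, n),
                    fs = fs, onset_sample = n_pre + 1, offset_sample = n,
                    preictal_samples = n_pre)
}

# single-drug schedule fixture
single_dose_schedule <- function(times = 0, dose = 100, ka = 1, ke = 0.1) {
  dose_schedule(
    data.frame(drug = "d1", dose_mg = dose, time_h = times),
    list(d1 = list(ka = ka, ke = ke, scale = 0.01)))
}

# planted pattern matrix with disjoint region blocks; one band per state
toy_W <- function(n_regions, states_bands) {
  W <- matrix(0, n_regions * 6, length(states_bands))
  block <- floor(n_regions / length(states_bands))
  for (j in seq_along(states_bands)) {
    regs <- ((j - 1) * block + 1):(j * block)
    for (r in regs) W[(r - 1) * 6 + states_bands[j], j] <- 1
  }
  W
}

# match recovered labels to planted ids via pattern matching; returns the
# relabelled recovered sequence
relabel_states <- function(recovered, W_fit, W_true) {
  mt <- taperstates:::match_states(W_fit, W_true)
  out <- recovered
  out[recovered > 0] <- mt$perm[recovered[recovered > 0]]
  out
}

# ground-truth-driven taper-analysis input for permutation tests
gt_subject_inputs <- function(cohort) {
  lapply(names(cohort$ground_truth), function(s) {
    sz <- cohort$seizures[cohort$seizures$subject == s, , drop = FALSE]
    list(sequences = cohort$ground_truth[[s]]$sequences,
         conditions = sz$condition,
         n_states = cohort$config$n_states_per_subject,
         log10_duration = sz$log10_duration)
  })
}
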