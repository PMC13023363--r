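# -- Synthetic cohort generator -----------------------------------------------
#
# Generates cohorts with known ground truth so every downstream stage has a
# parameter-recovery surface. Two tiers: a feature tier (region x band
# z-score arrays with planted state patterns) and a signal tier (raw
# multichannel time series whose band power realizes those patterns).
#
# The data-generating model mirrors the analysis model: seizure onsets follow
# a piecewise-constant-rate Poisson process (typical rate before the taper,
# tapered rate after); log10 duration is a subject offset plus a linear ASM
# effect, 24 h and 12 h sinusoids of onset clock time, an additive bonus for
# seizures containing a taper-emergent state, and Gaussian noise; planted
# taper-emergent states are gated to occur only when the ASM level is below
# the gate threshold.

#' Synthetic cohort configuration
#'
#' Defaults describe a cohort of 28 subjects monitored ~10 days with a taper
#' starting on day 3, an ASM-level duration slope of -0.033 log10-seconds per
#' normalized unit, subtle circadian modulation, and a five-fold seizure-rate
#' increase under tapering.
#'
#' @param n_subjects number of subjects.
#' @param regions_per_subject recorded brain regions per subject (must be >=
#'   `n_states_per_subject` so planted states can have disjoint region
#'   support).
#' @param n_states_per_subject number of planted states.
#' @param n_taper_emergent planted taper-emergent states (strictly fewer than
#'   the states per subject; 0 allowed).
#' @param tes_gate_level ASM level below which TES states may occur.
#' @param beta0_mean,beta0_sd mean and SD of per-subject log10-seconds
#'   duration offsets.
#' @param beta1 duration slope, log10-seconds per normalized ASM unit.
#' @param circ_amp_24h,circ_amp_12h amplitudes of the planted sin(2*pi*T/24)
#'   and sin(2*pi*T/12) duration terms, log10-seconds.
#' @param noise_sd residual SD of log10 duration.
#' @param rate_typical,rate_tapered seizure rates, per day.
#' @param taper_start_day day the taper begins (doses shrink thereafter).
#' @param taper_slope fraction of the pre-taper dose removed per day of
#'   taper.
#' @param n_days total observation days.
#' @param tes_bonus additive log10-seconds duration bonus for TES-containing
#'   seizures.
#' @param tes_seizure_prob probability that a below-gate seizure carries at
#'   least one TES state (TES occurrence is sparse in observed cohorts:
#'   roughly 4 of 11 seizures in subjects that have such states).
#' @param expression_gain planted expression amplitude of the active state in
#'   z-units.
#' @param seed integer RNG seed; a fixed seed makes the cohort byte-identical
#'   across calls.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 28,
                             regions_per_subject = 10,
                             n_states_per_subject = 5,
                             n_taper_emergent = 2,
                             tes_gate_level = -1,
                             beta0_mean = 1.85,
                             beta0_sd = 0.3,
                             beta1 = -0.033,
                             circ_amp_24h = 0.05,
                             circ_amp_12h = 0.03,
                             noise_sd = 0.2,
                             rate_typical = 0.5,
                             rate_tapered = 2.5,
                             taper_start_day = 3,
                             taper_slope = 0.33,
                             n_days = 10,
                             tes_bonus = 0.3,
                             tes_seizure_prob = 0.4,
                             expression_gain = 3,
                             seed = 1L) {
  cfg <- list(n_subjects = n_subjects,
              regions_per_subject = regions_per_subject,
              n_states_per_subject = n_states_per_subject,
              n_taper_emergent = n_taper_emergent,
              tes_gate_level = tes_gate_level,
              beta0_mean = beta0_mean, beta0_sd = beta0_sd, beta1 = beta1,
              circ_amp_24h = circ_amp_24h, circ_amp_12h = circ_amp_12h,
              noise_sd = noise_sd,
              rate_typical = rate_typical, rate_tapered = rate_tapered,
              taper_start_day = taper_start_day, taper_slope = taper_slope,
              n_days = n_days, tes_bonus = tes_bonus,
              tes_seizure_prob = tes_seizure_prob,
              expression_gain = expression_gain,
              seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1 || regions_per_subject < 1 || n_states_per_subject < 1)
      stop("counts must be >= 1")
    if (n_taper_emergent < 0 || n_taper_emergent >= n_states_per_subject)
      stop("n_taper_emergent must be in [0, n_states_per_subject)")
    if (regions_per_subject < n_states_per_subject)
      stop("need at least one region per planted state")
    if (noise_sd < 0 || beta0_sd < 0) stop("SDs must be non-negative")
    if (rate_typical < 0 || rate_tapered < 0) stop("rates must be >= 0")
    if (taper_start_day <= 0 || taper_start_day >= n_days)
      stop("taper_start_day must lie inside the observation window")
  })
  structure(cfg, class = "synthetic_config")
}

# sample that treats a length-1 vector as a set, not as 1:n
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# disjoint-support planted pattern matrix: state j is active on its own block
# of regions in 1-2 bands, entries in (0.5, 1], unit column maximum
make_w_true <- function(n_regions, n_states, n_bands = 6) {
  W <- matrix(0, n_regions * n_bands, n_states)
  block <- floor(n_regions / n_states)
  for (j in seq_len(n_states)) {
    regs <- ((j - 1) * block + 1):(j * block)
    bands_j <- sort(sample(n_bands, sample(1:2, 1)))
    for (r in regs) for (b in bands_j)
      W[(r - 1) * n_bands + b, j] <- stats::runif(1, 0.5, 1)
  }
  sweep(W, 2, apply(W, 2, max), "/")
}

# standard twice-daily schedule with a linear taper of the dose
make_dosing <- function(subject, cfg, drug = "levetiracetam",
                        dose_mg = 500, lead_in_days = 3) {
  days <- seq(-lead_in_days, cfg$n_days - 1)
  rows <- list()
  for (d in days) {
    mult <- if (d < cfg$taper_start_day) 1
    else max(0, 1 - cfg$taper_slope * (d - cfg$taper_start_day + 1))
    if (mult <= 0) next
    for (clock in c(8, 20))
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, drug = drug, dose_mg = dose_mg * mult,
        time_h = d * 24 + clock)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' Returns dosing schedules, seizure annotations (including non-lead seizures
#' so the inclusion filter downstream is exercised), per-seizure feature
#' arrays (feature tier), and a ground-truth sidecar. The retained-seizure
#' table applies the 120 s lead-seizure rule and drops excluded-condition
#' seizures, matching what pipeline ingestion should produce.
#'
#' @param config a [synthetic_config()].
#' @param tier `"features"` (region x band z arrays; default) or `"none"`
#'   (tables only; the signal tier is produced per seizure by
#'   [synthesize_signal()]).
#' @param pk_params per-drug PK parameters (default: bundled file).
#' @return list of class `synthetic_cohort`: `config`, `dosing`,
#'   `annotations`, `seizures` (retained ground-truth seizure table),
#'   `features` (per subject, per retained seizure), `ground_truth` (per
#'   subject: `W_true`, `sequences`, `tes_ids`, `beta0`), `levels` (per
#'   subject labelled ASM level series), `condition_days`.
#' @export
generate_cohort <- function(config, tier = c("features", "none"),
                            pk_params = load_pk_params()) {
  stopifnot(inherits(config, "synthetic_config"))
  tier <- match.arg(tier)
  cfg <- config
  set.seed(cfg$seed)
  n_bands <- 6
  subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))

  dosing_all <- list(); ann_all <- list(); seiz_all <- list()
  features <- list(); gt <- list(); levels_all <- list(); cdays_all <- list()

  for (si in seq_along(subjects)) {
    s <- subjects[si]
    beta0 <- stats::rnorm(1, cfg$beta0_mean, cfg$beta0_sd)
    W_true <- make_w_true(cfg$regions_per_subject, cfg$n_states_per_subject,
                          n_bands)
    tes_ids <- if (cfg$n_taper_emergent > 0)
      (cfg$n_states_per_subject - cfg$n_taper_emergent + 1):
        cfg$n_states_per_subject else integer(0)
    di_ids <- setdiff(seq_len(cfg$n_states_per_subject), tes_ids)

    dosing <- make_dosing(s, cfg)
    sched <- dose_schedule(dosing[c("drug", "dose_mg", "time_h")], pk_params)
    lv <- asm_level_series(sched,
                           t_span = c(-12, cfg$n_days * 24 + 12),
                           steady_interval = c(0, cfg$taper_start_day * 24))

    # condition-locked Poisson onsets by thinning: candidates at the maximum
    # rate, accepted with probability rate(level at t)/rate_max, where the
    # level is the same interpolated series used to label conditions. The
    # tapered rate therefore applies exactly where the analysis will label
    # "tapered" (the plasma kinetics lag the nominal taper start).
    rate_max <- max(cfg$rate_typical, cfg$rate_tapered)
    n_cand <- stats::rpois(1, rate_max * cfg$n_days)
    cand <- sort(stats::runif(n_cand, 0, cfg$n_days * 24))
    lvl_cand <- level_at(lv, cand)
    r_cand <- ifelse(lvl_cand < -1, cfg$rate_tapered, cfg$rate_typical)
    onset_h <- cand[stats::runif(n_cand) < r_cand / rate_max]
    n_sz <- length(onset_h)
    if (n_sz == 0) next
    level <- level_at(lv, onset_h)
    condition <- as.character(cut(level, c(-Inf, -1, 1, Inf),
                                  labels = c("tapered", "typical", "excluded")))
    gated <- level < cfg$tes_gate_level

    # per-seizure state sets: TES states are eligible only below the gate
    # level, and even there occur sparsely (tes_seizure_prob)
    seq_states <- vector("list", n_sz)
    for (i in seq_len(n_sz)) {
      carry_tes <- gated[i] && length(tes_ids) > 0 &&
        stats::runif(1) < cfg$tes_seizure_prob
      if (carry_tes) {
        k <- sample.int(min(3, cfg$n_states_per_subject), 1)
        first <- resample(tes_ids, 1)
        rest <- setdiff(c(di_ids, tes_ids), first)
        seq_states[[i]] <- resample(c(first, resample(rest, k - 1)))
      } else {
        k <- sample.int(min(3, length(di_ids)), 1)
        seq_states[[i]] <- resample(di_ids, k)
      }
    }
    contains_tes <- vapply(seq_states, function(v) any(v %in% tes_ids),
                           logical(1))

    clock <- onset_h %% 24
    log_dur <- beta0 + cfg$beta1 * level +
      cfg$circ_amp_24h * sin(2 * pi * clock / 24) +
      cfg$circ_amp_12h * sin(2 * pi * clock / 12) +
      cfg$tes_bonus * contains_tes +
      stats::rnorm(n_sz, 0, cfg$noise_sd)
    duration <- pmax(10^log_dur, 6)
    offset_h <- onset_h + duration / 3600

    # drop seizures that would overlap the previous kept one (Poisson draws
    # occasionally land inside an ongoing seizure); keeps the first of a pair
    keep <- rep(TRUE, n_sz)
    last_off <- -Inf
    for (i in seq_len(n_sz)) {
      if (onset_h[i] * 3600 < last_off + 1) keep[i] <- FALSE
      else last_off <- offset_h[i] * 3600
    }
    sub <- function(x) x[keep]
    onset_h <- sub(onset_h); offset_h <- sub(offset_h); level <- sub(level)
    condition <- sub(condition); gated <- sub(gated); clock <- sub(clock)
    duration <- sub(duration); contains_tes <- sub(contains_tes)
    seq_states <- seq_states[keep]
    n_sz <- sum(keep)
    if (n_sz == 0) next

    ann <- data.frame(subject = s,
                      onset_s = onset_h * 3600,
                      offset_s = offset_h * 3600,
                      sleep_deprivation = FALSE, stimulation = FALSE,
                      excluded_period = FALSE)
    lead <- select_lead_seizures(ann)
    retained <- lead$retained & condition != "excluded"
    drop_reason <- ifelse(!lead$retained, lead$drop_reason,
                          ifelse(condition == "excluded",
                                 "excluded_level", ""))

    # coverage enforcement on the retained set, preserving each seizure's
    # contains-TES flag (so durations stay consistent with the model):
    # every planted dose-independent state is anchored in a typical-condition
    # seizure; every planted TES state is carried by a seizure that already
    # contains a TES state
    typ_idx <- which(retained & condition == "typical")
    if (length(typ_idx)) for (j in seq_along(di_ids)) {
      id <- di_ids[j]
      if (!any(vapply(seq_states[typ_idx], function(v) id %in% v, logical(1)))) {
        tgt <- typ_idx[(j - 1) %% length(typ_idx) + 1]
        seq_states[[tgt]] <- c(seq_states[[tgt]], id)
      }
    }
    carrier_idx <- which(retained & contains_tes)
    if (length(carrier_idx)) for (j in seq_along(tes_ids)) {
      id <- tes_ids[j]
      if (!any(vapply(seq_states[carrier_idx], function(v) id %in% v,
                      logical(1)))) {
        tgt <- carrier_idx[(j - 1) %% length(carrier_idx) + 1]
        seq_states[[tgt]] <- c(seq_states[[tgt]], id)
      }
    }

    # windowed label vectors (5 s window, 1 s hop; last partial dropped)
    n_windows <- pmax(floor((duration - 5) / 1) + 1, 1)
    label_seqs <- vector("list", n_sz)
    for (i in seq_len(n_sz)) {
      st <- seq_states[[i]]
      k <- length(st)
      nT <- n_windows[i]
      if (k > nT) { st <- st[seq_len(nT)]; k <- nT }
      lens <- as.vector(stats::rmultinom(1, nT - k, rep(1, k))) + 1
      label_seqs[[i]] <- rep(st, times = lens)
    }

    feat <- NULL
    if (tier == "features") {
      feat <- lapply(which(retained), function(i) {
        lab <- label_seqs[[i]]
        nT <- length(lab)
        z <- array(0, c(cfg$regions_per_subject, n_bands, nT))
        for (w in seq_len(nT)) {
          col <- cfg$expression_gain * W_true[, lab[w]]
          z[, , w] <- t(matrix(col, n_bands, cfg$regions_per_subject))
        }
        if (cfg$noise_sd > 0)
          z <- z + array(stats::rnorm(length(z), 0, cfg$noise_sd), dim(z))
        structure(list(z = z,
                       regions = sprintf("r%02d", seq_len(cfg$regions_per_subject)),
                       bands = rownames(band_edges()),
                       window_starts_s = seq_len(nT) - 1,
                       n_windows = nT),
                  class = "region_band_features")
      })
    }

    # observed days per condition from the labelled level series
    span_sel <- lv$time_h >= 0 & lv$time_h <= cfg$n_days * 24
    step_days <- diff(lv$time_h[1:2]) / 24
    cd <- data.frame(subject = s,
                     condition = c("typical", "tapered"),
                     days = c(sum(lv$condition[span_sel] == "typical"),
                              sum(lv$condition[span_sel] == "tapered")) * step_days)

    seiz <- data.frame(subject = s, onset_h = onset_h, clock_h = clock,
                       onset_s = ann$onset_s, offset_s = ann$offset_s,
                       duration_s = duration, log10_duration = log10(duration),
                       asm_level = level, condition = condition,
                       contains_tes = contains_tes,
                       retained = retained, drop_reason = drop_reason)

    dosing_all[[s]] <- dosing
    ann_all[[s]] <- ann
    seiz_all[[s]] <- seiz
    features[[s]] <- feat
    gt[[s]] <- list(W_true = W_true,
                    sequences = label_seqs[retained],
                    sequences_all = label_seqs,
                    tes_ids = tes_ids, beta0 = beta0)
    levels_all[[s]] <- lv
    cdays_all[[s]] <- cd
  }

  structure(list(config = cfg,
                 dosing = do.call(rbind, dosing_all),
                 annotations = do.call(rbind, ann_all),
                 seizures_all = do.call(rbind, seiz_all),
                 seizures = {
                   tab <- do.call(rbind, seiz_all)
                   rownames(tab) <- NULL
                   tab[tab$retained, , drop = FALSE]
                 },
                 features = features,
                 ground_truth = gt,
                 levels = levels_all,
                 condition_days = do.call(rbind, cdays_all)),
            class = "synthetic_cohort")
}

#' Synthesize a raw multichannel seizure clip from a state sequence
#'
#' One channel per region. The clip is baseline Gaussian noise (flat
#' broadband, also filling the 120 s pre-ictal lead-in); during the seizure,
#' band-limited Gaussian noise shaped by the active state's pattern column is
#' added: for each (region, band) entry of `W_true`, noise band-passed to
#' that band, scaled by `gain` times the entry, on top of the baseline. Band
#' power in each window is therefore monotone in the active column's entries.
#'
#' @param state_sequence integer labels per analysis window (5 s window, 1 s
#'   hop).
#' @param W_true (regions*6) x n_states non-negative pattern matrix, unit
#'   column maxima.
#' @param fs sampling rate, Hz (>= 256).
#' @param gain amplitude scaling of planted band-limited activity relative to
#'   the unit-SD baseline.
#' @param preictal_s pre-ictal lead-in, seconds.
#' @param seed RNG seed.
#' @return a [seizure_recording()].
#' @export
synthesize_signal <- function(state_sequence, W_true, fs = 512, gain = 4,
                              preictal_s = 120, seed = 1L) {
  if (fs < 256) stop("fs must be >= 256 Hz")
  n_bands <- 6
  n_regions <- nrow(W_true) / n_bands
  stopifnot(n_regions == round(n_regions))
  if (any(state_sequence < 0 | state_sequence > ncol(W_true)))
    stop("unknown state id in sequence")   # 0 = null state (baseline only)
  set.seed(seed)
  nT <- length(state_sequence)
  ictal_s <- (nT - 1) * 1 + 5
  n_pre <- round(preictal_s * fs)
  n_ict <- round(ictal_s * fs)
  n <- n_pre + n_ict
  edges <- band_edges()
  nyq <- fs / 2
  # per-sample state id over the ictal span (window whose start covers t)
  tt <- (seq_len(n_ict) - 1) / fs
  widx <- pmin(floor(tt) + 1, nT)
  sig <- matrix(stats::rnorm(n_regions * n, 0, 1), n_regions, n)
  for (r in seq_len(n_regions)) {
    for (b in seq_len(n_bands)) {
      w_rb <- W_true[(r - 1) * n_bands + b, ]
      wt <- numeric(nT)                      # null windows stay at baseline
      wt[state_sequence > 0] <- w_rb[state_sequence[state_sequence > 0]]
      if (all(wt == 0)) next
      bf <- signal::butter(2, edges[b, ] / nyq, type = "pass")
      bn <- signal::filtfilt(bf, stats::rnorm(n_ict))
      bn <- bn / stats::sd(bn)
      env <- gain * wt[widx]
      sig[r, n_pre + seq_len(n_ict)] <- sig[r, n_pre + seq_len(n_ict)] + env * bn
    }
  }
  seizure_recording(sig, fs,
                    onset_sample = n_pre + 1L, offset_sample = n,
                    channel_ids = sprintf("r%02d", seq_len(n_regions)),
                    preictal_samples = n_pre)
}
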