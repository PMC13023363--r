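# -- iEEG pre-processing ------------------------------------------------------
#
# Seizure clips arrive as channels x samples matrices with a 120 s pre-ictal
# lead-in. Processing: resample to 512 Hz (anti-aliased), zero-phase 4th-order
# Butterworth band-pass 0.5-200 Hz plus 2 Hz-wide notches at 50 Hz and
# harmonics, subject-wide noisy-channel exclusion, common-average
# re-referencing, and the seizure inclusion rules (lead seizures only,
# flagged/excluded-period seizures dropped).

#' Construct a seizure recording
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param onset_sample,offset_sample seizure onset/offset sample indices
#'   (1-based) within the clip.
#' @param channel_ids character channel labels (default ch1..chN).
#' @param preictal_samples number of samples before `onset_sample` forming the
#'   pre-ictal baseline (target 120 s).
#' @return object of class `seizure_recording`.
#' @export
seizure_recording <- function(signal, fs, onset_sample, offset_sample,
                              channel_ids = NULL,
                              preictal_samples = onset_sample - 1L) {
  stopifnot(is.matrix(signal), fs > 0,
            onset_sample >= 1, onset_sample < offset_sample,
            offset_sample <= ncol(signal),
            preictal_samples < onset_sample)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(signal)))
  stopifnot(length(channel_ids) == nrow(signal))
  rownames(signal) <- channel_ids
  structure(list(signal = signal, fs = fs,
                 channel_ids = channel_ids,
                 onset_sample = as.integer(onset_sample),
                 offset_sample = as.integer(offset_sample),
                 preictal_samples = as.integer(preictal_samples)),
            class = "seizure_recording")
}

#' Resample a recording to 512 Hz with anti-aliasing
#'
#' Zero-phase (forward-backward Butterworth) anti-alias low-pass at 0.45
#' times the target rate, then exact decimation for integer rate ratios or
#' spline interpolation at the new sample times otherwise. Recordings already
#' at 512 Hz pass through unchanged. Onset/offset marks are rescaled to the
#' new rate. Upsampling is not supported: clips below 512 Hz should be
#' configured to bypass this step.
#'
#' @param rec a [seizure_recording()].
#' @return resampled `seizure_recording` at 512 Hz.
#' @export
resample_to_512 <- function(rec) {
  stopifnot(inherits(rec, "seizure_recording"))
  if (rec$fs < 512)
    stop("sampling rate below 512 Hz; upsampling unsupported - ",
         "configure the pipeline to pass this clip through unresampled")
  if (rec$fs == 512) return(rec)
  aa <- signal::butter(4, 2 * 0.45 * 512 / rec$fs, type = "low")
  q <- rec$fs / 512
  n_new <- floor(ncol(rec$signal) / q)
  new_sig <- t(apply(rec$signal, 1, function(x) {
    y <- signal::filtfilt(aa, x)
    if (q == round(q)) y[seq(1, by = q, length.out = n_new)]
    else stats::spline(seq_along(y), y,
                       xout = 1 + (seq_len(n_new) - 1) * q)$y
  }))
  scale <- 512 / rec$fs
  new_onset <- max(1L, round(rec$onset_sample * scale))
  seizure_recording(new_sig, 512,
                    onset_sample = new_onset,
                    offset_sample = min(ncol(new_sig),
                                        round(rec$offset_sample * scale)),
                    channel_ids = rec$channel_ids,
                    preictal_samples = min(round(rec$preictal_samples * scale),
                                           new_onset - 1L))
}

#' Zero-phase band-pass and notch filtering
#'
#' Forward-backward (zero group delay) 4th-order Butterworth band-pass
#' 0.5-200 Hz, followed by 4th-order Butterworth band-stop notches of total
#' width 2 Hz (f-1 to f+1 Hz) at 50 Hz and its harmonics up to 200 Hz,
#' applied per channel.
#'
#' @param rec a [seizure_recording()] at 512 Hz.
#' @param line_freq mains frequency, Hz (default 50).
#' @return filtered `seizure_recording`.
#' @export
filter_signal <- function(rec, line_freq = 50) {
  stopifnot(inherits(rec, "seizure_recording"))
  if (rec$fs != 512) stop("filter_signal expects a 512 Hz recording")
  if (!all(is.finite(rec$signal))) stop("non-finite samples in signal")
  nyq <- rec$fs / 2
  # band-pass as a high-/low-pass cascade (numerically better conditioned
  # than one band-pass polynomial at a 0.5 Hz edge): 2 poles per edge, i.e. a
  # 4th-order band-pass overall
  hp <- signal::butter(2, 0.5 / nyq, type = "high")
  lp <- signal::butter(2, 200 / nyq, type = "low")
  harmonics <- seq(line_freq, 200, by = line_freq)
  notches <- lapply(harmonics, function(f)
    signal::butter(2, c(f - 1, f + 1) / nyq, type = "stop"))
  filt_one <- function(x) {
    x <- x - mean(x)   # demean first: the slow 0.5 Hz pole leaves a tiny
    # numerical DC residue otherwise
    y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
    for (nf in notches) y <- signal::filtfilt(nf, y)
    y
  }
  rec$signal <- t(apply(rec$signal, 1, filt_one))
  rownames(rec$signal) <- rec$channel_ids
  rec
}

#' Iterative noisy-channel detection for one subject
#'
#' The detection rule (the field typically pairs an automatic screen with
#' visual validation; this screen is deterministic and is labelled as such in
#' reports): compute each channel's log variance over the pre-ictal segments
#' of all the subject's recordings, robust-z-score across retained channels
#' (median and scaled MAD, which resists masking by the outliers being
#' screened for), flag |z| > 3, and iterate on the retained set until a fixed
#' point. The result is unioned with a user-supplied manual list and applied
#' subject-wide.
#'
#' @param recordings list of [seizure_recording()] for one subject (same
#'   channel set).
#' @param manual_bad character vector of channel ids to exclude regardless.
#' @param z_thresh flag threshold on |z| of log variance (default 3).
#' @return data.frame `channel`, `excluded`, `reason` ("auto", "manual",
#'   "auto+manual" or "").
#' @export
detect_noisy_channels <- function(recordings, manual_bad = character(),
                                  z_thresh = 3) {
  stopifnot(length(recordings) >= 1)
  ids <- recordings[[1]]$channel_ids
  for (r in recordings) stopifnot(identical(r$channel_ids, ids))
  # pooled preictal variance per channel across recordings
  pre_var <- sapply(recordings, function(r) {
    seg <- r$signal[, seq_len(max(r$preictal_samples, 2)), drop = FALSE]
    apply(seg, 1, stats::var)
  })
  if (is.null(dim(pre_var))) pre_var <- matrix(pre_var, nrow = length(ids))
  logv <- log10(rowMeans(pre_var) + .Machine$double.eps)
  auto <- rep(FALSE, length(ids))
  repeat {
    kept <- which(!auto)
    if (length(kept) < 3) break
    med <- stats::median(logv[kept])
    scale_ <- stats::mad(logv[kept], center = med)
    if (!is.finite(scale_) || scale_ == 0) break   # (near-)identical channels
    z <- (logv[kept] - med) / scale_
    new_flags <- kept[abs(z) > z_thresh]
    if (!length(new_flags)) break
    auto[new_flags] <- TRUE
  }
  manual <- ids %in% manual_bad
  reason <- ifelse(auto & manual, "auto+manual",
                   ifelse(auto, "auto", ifelse(manual, "manual", "")))
  out <- data.frame(channel = ids, excluded = auto | manual,
                    reason = reason, stringsAsFactors = FALSE)
  if (all(out$excluded)) stop("all channels flagged; subject unusable")
  out
}

#' Common-average re-referencing
#'
#' Excluded channels are dropped, then each retained channel has the
#' per-sample mean over retained channels subtracted.
#'
#' @param rec a [seizure_recording()].
#' @param quality optional channel-quality data.frame from
#'   [detect_noisy_channels()]; excluded channels are removed first.
#' @return re-referenced `seizure_recording` containing retained channels
#'   only.
#' @export
common_average_reference <- function(rec, quality = NULL) {
  stopifnot(inherits(rec, "seizure_recording"))
  keep <- rec$channel_ids
  if (!is.null(quality))
    keep <- setdiff(keep, quality$channel[quality$excluded])
  if (length(keep) < 2) stop("fewer than 2 retained channels; CAR undefined")
  sig <- rec$signal[keep, , drop = FALSE]
  sig <- sweep(sig, 2, colMeans(sig))
  rec$signal <- sig
  rec$channel_ids <- keep
  rec
}

#' Apply the seizure inclusion rules to an annotation table
#'
#' Seizures in quick succession (< 120 s from the previous retained seizure's
#' offset to the next onset) are reduced to the lead seizure. Rows flagged as
#' following sleep deprivation or cortical stimulation, or as occurring in an
#' excluded ASM period (e.g. rescue medication), are dropped with the reason
#' logged.
#'
#' @param ann data.frame with `subject`, `onset_s`, `offset_s` (seconds on a
#'   common clock per subject) and optional logical columns
#'   `sleep_deprivation`, `stimulation`, `excluded_period`.
#' @param min_gap_s minimum offset-to-onset gap in seconds (default 120).
#' @return `ann` with logical `retained` and character `drop_reason` columns.
#' @export
select_lead_seizures <- function(ann, min_gap_s = 120) {
  stopifnot(all(c("subject", "onset_s", "offset_s") %in% names(ann)))
  for (fl in c("sleep_deprivation", "stimulation", "excluded_period"))
    if (is.null(ann[[fl]])) ann[[fl]] <- FALSE
  ann$retained <- TRUE
  ann$drop_reason <- ""
  for (s in unique(ann$subject)) {
    idx <- which(ann$subject == s)
    idx <- idx[order(ann$onset_s[idx])]
    on <- ann$onset_s[idx]; off <- ann$offset_s[idx]
    if (any(on[-1] < off[-length(off)] - 1e-9) && length(idx) > 1)
      stop("overlapping seizures for subject ", s)
    flag_drop <- ann$sleep_deprivation[idx] | ann$stimulation[idx] |
      ann$excluded_period[idx]
    last_off <- -Inf
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (flag_drop[k]) {
        ann$retained[i] <- FALSE
        ann$drop_reason[i] <- paste(
          c("sleep_deprivation", "stimulation", "excluded_period")[
            c(ann$sleep_deprivation[i], ann$stimulation[i],
              ann$excluded_period[i])], collapse = "+")
        next
      }
      # gap measured to the most recent RETAINED seizure's offset
      if (on[k] - last_off < min_gap_s) {
        ann$retained[i] <- FALSE
        ann$drop_reason[i] <- "non_lead"
      } else {
        last_off <- off[k]
      }
    }
  }
  ann
}
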