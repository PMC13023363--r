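# -- Taper-emergent state analysis --------------------------------------------
#
# Within each eligible subject (at least three seizures, with at least one in
# each of the tapered and typical ASM conditions), a state is
# "taper-emergent" (TES) when every seizure it occurs in belongs to the
# tapered condition; all other states are "dose-independent". Seizures are
# then categorized (TES-containing / tapered without TES / typical), TES
# duration proportions and first-appearance ordinals are computed, and a
# within-subject permutation null quantifies whether the extra duration of
# TES-containing seizures exceeds chance.

#' State-by-seizure occurrence counts for one subject
#'
#' @param sequences list of integer state-label vectors, one per seizure
#'   (0 = null state).
#' @param n_states number of non-null states.
#' @return matrix n_states x n_seizures of window counts.
#' @export
state_occurrence <- function(sequences, n_states) {
  sapply(sequences, function(s) tabulate(s[s > 0], nbins = n_states))
}

#' Classify states as taper-emergent or dose-independent
#'
#' A subject is eligible when it has at least `min_seizures` seizures overall
#' and at least one in each of the tapered and typical conditions; ineligible
#' subjects are skipped (NULL with a reason attribute). A state "occurs" in a
#' seizure when it is assigned at least `min_windows` windows there. A state
#' is taper-emergent iff all the seizures it occurs in are in the tapered
#' condition (and it occurs at least once).
#'
#' @param sequences list of per-seizure integer label vectors for one
#'   subject.
#' @param conditions character vector per seizure: "tapered" or "typical".
#' @param n_states number of non-null states.
#' @param min_windows minimum assigned windows for a state to count as
#'   occurring in a seizure (default 1).
#' @param min_seizures eligibility threshold (default 3).
#' @return data.frame `state`, `class` ("taper_emergent" /
#'   "dose_independent" / "absent"), `n_tapered`, `n_typical`; or NULL (with
#'   a message giving the reason) if the subject is ineligible.
#' @export
classify_states <- function(sequences, conditions, n_states,
                            min_windows = 1, min_seizures = 3) {
  stopifnot(length(sequences) == length(conditions))
  conditions <- as.character(conditions)
  eligible <- length(sequences) >= min_seizures &&
    any(conditions == "tapered") && any(conditions == "typical")
  if (!eligible) {
    message(sprintf(
      "subject skipped - ineligible: %d seizures (%d tapered, %d typical)",
      length(sequences), sum(conditions == "tapered"),
      sum(conditions == "typical")))
    return(NULL)
  }
  occ <- state_occurrence(sequences, n_states) >= min_windows
  if (is.null(dim(occ))) occ <- matrix(occ, nrow = n_states)
  n_tap <- rowSums(occ[, conditions == "tapered", drop = FALSE])
  n_typ <- rowSums(occ[, conditions == "typical", drop = FALSE])
  cls <- ifelse(n_tap + n_typ == 0, "absent",
                ifelse(n_typ == 0, "taper_emergent", "dose_independent"))
  data.frame(state = seq_len(n_states), class = cls,
             n_tapered = n_tap, n_typical = n_typ,
             stringsAsFactors = FALSE)
}

#' Categorize seizures by condition and TES content
#'
#' @param sequences per-seizure label vectors.
#' @param state_class output of [classify_states()] for the same subject.
#' @param conditions per-seizure condition.
#' @param min_windows as in [classify_states()].
#' @return character vector per seizure: `"tes"` (tapered, contains a
#'   taper-emergent state), `"tapered_no_tes"`, `"typical"`.
#' @export
categorize_seizures <- function(sequences, state_class, conditions,
                                min_windows = 1) {
  tes_ids <- state_class$state[state_class$class == "taper_emergent"]
  vapply(seq_along(sequences), function(i) {
    counts <- tabulate(sequences[[i]][sequences[[i]] > 0],
                       nbins = nrow(state_class))
    has_tes <- any(counts[tes_ids] >= min_windows)
    if (has_tes && conditions[i] != "tapered")
      stop("typical-condition seizure contains a taper-emergent state; ",
           "classification is inconsistent")
    if (has_tes) "tes"
    else if (conditions[i] == "tapered") "tapered_no_tes"
    else "typical"
  }, character(1))
}

#' TES duration proportion and first-appearance ordinal per seizure
#'
#' For each TES-containing seizure: the proportion of its non-null windows
#' labelled with a taper-emergent state, and the ordinal position of the
#' first TES state in the run-length-encoded state sequence (1 = the seizure
#' starts in a TES state).
#'
#' @param sequences per-seizure label vectors.
#' @param state_class output of [classify_states()].
#' @return data.frame `seizure`, `proportion`, `first_ordinal` (one row per
#'   TES-containing seizure; empty if none).
#' @export
tes_duration_stats <- function(sequences, state_class) {
  tes_ids <- state_class$state[state_class$class == "taper_emergent"]
  rows <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    nn <- s[s > 0]
    if (!length(nn) || !any(nn %in% tes_ids)) return(NULL)
    prop <- sum(nn %in% tes_ids) / length(nn)
    runs <- rle(nn)$values
    ord <- which(runs %in% tes_ids)[1]
    data.frame(seizure = i, proportion = prop, first_ordinal = ord)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seizure = integer(), proportion = numeric(),
                      first_ordinal = integer())
  out
}

#' Permutation null for the TES duration effect
#'
#' Observed effect: rank-sum z of log10 duration, TES-containing versus all
#' other seizures, over subjects that have taper-emergent states. Null: the
#' per-seizure condition labels are shuffled within each subject (preserving
#' that subject's condition counts), pseudo-TES states are re-derived from
#' the shuffled labels, seizures re-categorized, and the effect recomputed.
#' p is the fraction of permuted effects at least as large as the observed
#' one (one-sided, "TES-containing longer").
#'
#' @param subjects list, one element per subject, each a list with
#'   `sequences` (per-seizure labels), `conditions`, `n_states`,
#'   `log10_duration` (per seizure).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param min_windows,min_seizures as in [classify_states()].
#' @return list: `observed` (z), `null` (numeric n_perm), `p`.
#' @export
permutation_null_tes_effect <- function(subjects, n_perm = 1000, seed = 1L,
                                        min_windows = 1, min_seizures = 3) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  effect <- function(cond_list) {
    dur_tes <- c(); dur_other <- c()
    for (i in seq_along(subjects)) {
      su <- subjects[[i]]
      cl <- suppressMessages(
        classify_states(su$sequences, cond_list[[i]], su$n_states,
                        min_windows, min_seizures))
      if (is.null(cl)) next
      if (!any(cl$class == "taper_emergent")) next
      cat_i <- tryCatch(
        categorize_seizures(su$sequences, cl, cond_list[[i]], min_windows),
        error = function(e) NULL)
      if (is.null(cat_i)) next
      dur_tes <- c(dur_tes, su$log10_duration[cat_i == "tes"])
      dur_other <- c(dur_other, su$log10_duration[cat_i != "tes"])
    }
    if (!length(dur_tes) || !length(dur_other)) return(NA_real_)
    wilcoxon_rank_sum(dur_tes, dur_other)$z
  }
  obs <- effect(lapply(subjects, function(s) as.character(s$conditions)))
  if (is.na(obs))
    stop("no TES-containing seizures; nothing to permute")
  n_total <- sum(vapply(subjects, function(s) length(s$conditions), integer(1)))
  if (n_total < 4) stop("too few seizures to permute")
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    perm <- lapply(subjects, function(s) sample(as.character(s$conditions)))
    effect(perm)
  }, numeric(1))
  p <- mean(null[!is.na(null)] >= obs)
  list(observed = obs, null = null, p = p)
}
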