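# -- Pipeline orchestration ---------------------------------------------------
#
# One call runs the full analysis on a synthetic cohort (or, with the
# lower-level functions, on user data): cohort generation, per-subject NMF
# state identification, ASM level estimation, taper-emergent state analysis,
# and the frequency/duration statistics, writing all intermediate tables and
# a human-readable report into a run directory.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Mirrors the analysis sequence frequency test -> duration mixed model ->
#' TES classification -> category model. All tables are written as CSV, model
#' summaries as JSON, and a `report.txt` ties the numbers together. Re-running
#' into a completed run directory is a no-op unless `force`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir run directory (created if needed).
#' @param nc `"auto"` for data-driven state-number selection or an integer
#'   override.
#' @param nc_candidates candidate state numbers for auto selection.
#' @param n_perm permutations for the TES duration null (0 disables).
#' @param force overwrite a completed run directory.
#' @return (invisibly) list with the cohort, per-subject state results, and
#'   the statistics; also written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, nc = "auto", nc_candidates = 1:6,
                         n_perm = 0, force = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    message("run directory already complete; use force = TRUE to redo")
    return(invisible(NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config)
  utils::write.csv(cohort$dosing, file.path(out_dir, "dosing.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$annotations, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$seizures, file.path(out_dir, "seizures.csv"),
                   row.names = FALSE)

  # per-subject state identification
  states <- list()
  state_rows <- list(); class_rows <- list()
  for (s in names(cohort$features)) {
    feats <- cohort$features[[s]]
    if (is.null(feats) || length(feats) < 2) next
    Xb <- build_X(feats)
    nc_s <- if (identical(nc, "auto"))
      select_nc(Xb, nc_candidates, seed = config$seed)
    else as.integer(nc)
    model <- fit_nmf(Xb$X, nc_s, seed = config$seed)
    seqs <- assign_states(model, Xb$index)
    sz <- cohort$seizures[cohort$seizures$subject == s, , drop = FALSE]
    cls <- classify_states(seqs$by_seizure, sz$condition, nc_s)
    cat_s <- if (!is.null(cls))
      categorize_seizures(seqs$by_seizure, cls, sz$condition)
    else rep(NA_character_, nrow(sz))
    states[[s]] <- list(model = model, sequences = seqs, nc = nc_s,
                        classes = cls, categories = cat_s)
    state_rows[[s]] <- data.frame(
      subject = s,
      seizure = rep(seq_along(seqs$by_seizure),
                    vapply(seqs$by_seizure, length, integer(1))),
      window = unlist(lapply(seqs$by_seizure, seq_along)),
      state = unlist(seqs$by_seizure))
    if (!is.null(cls)) class_rows[[s]] <- cbind(subject = s, cls)
  }
  if (length(state_rows))
    utils::write.csv(do.call(rbind, state_rows),
                     file.path(out_dir, "state_sequences.csv"),
                     row.names = FALSE)
  if (length(class_rows))
    utils::write.csv(do.call(rbind, class_rows),
                     file.path(out_dir, "state_classes.csv"),
                     row.names = FALSE)

  # attach categories to the seizure table
  seiz <- cohort$seizures
  seiz$category <- NA_character_
  for (s in names(states)) {
    idx <- which(seiz$subject == s)
    seiz$category[idx] <- states[[s]]$categories
  }
  utils::write.csv(seiz, file.path(out_dir, "seizure_table.csv"),
                   row.names = FALSE)

  # statistics
  freq <- seizure_frequency(seiz, cohort$condition_days)
  wide <- merge(freq[freq$condition == "typical", c("subject", "per_day")],
                freq[freq$condition == "tapered", c("subject", "per_day")],
                by = "subject", suffixes = c("_typical", "_tapered"))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  freq_test <- if (nrow(wide) >= 5)
    wilcoxon_signed_rank_paired(wide$per_day_tapered, wide$per_day_typical)
  else NULL

  lmm <- tryCatch(fit_duration_lmm(seiz), error = function(e) NULL)

  cat_lmm <- tryCatch({
    tes_subj <- names(states)[vapply(states, function(st)
      !is.null(st$classes) && any(st$classes$class == "taper_emergent"),
      logical(1))]
    fit_category_lmm(seiz[seiz$subject %in% tes_subj, , drop = FALSE])
  }, error = function(e) NULL)

  perm <- NULL
  if (n_perm > 0) {
    subj_in <- lapply(names(states), function(s) {
      sz <- seiz[seiz$subject == s, , drop = FALSE]
      list(sequences = states[[s]]$sequences$by_seizure,
           conditions = sz$condition, n_states = states[[s]]$nc,
           log10_duration = sz$log10_duration)
    })
    perm <- tryCatch(
      permutation_null_tes_effect(subj_in, n_perm = n_perm,
                                  seed = config$seed),
      error = function(e) NULL)
  }

  summary_out <- list(
    seed = config$seed,
    n_subjects = length(unique(seiz$subject)),
    n_seizures = nrow(seiz),
    frequency_effect = if (!is.null(freq_test))
      list(r = freq_test$r, z = freq_test$z, p = freq_test$p,
           n = freq_test$n),
    duration_lmm = if (!is.null(lmm))
      list(beta1 = lmm$beta1, se = lmm$beta1_se, p = lmm$beta1_p,
           percent_increase_per_unit_withdrawal =
             percent_change(lmm$beta1, "increase")),
    category_lmm = if (!is.null(cat_lmm))
      list(beta_tapered = cat_lmm$beta_tapered,
           beta_typical = cat_lmm$beta_typical),
    tes_permutation = if (!is.null(perm))
      list(observed_z = perm$observed, p = perm$p))
  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  report <- c(
    "Seizure-state / ASM taper analysis report",
    sprintf("subjects: %d, retained seizures: %d",
            summary_out$n_subjects, summary_out$n_seizures),
    if (!is.null(freq_test))
      sprintf("frequency, tapered vs typical (paired signed-rank): r = %.2f, p = %.3g",
              freq_test$r, freq_test$p),
    if (!is.null(lmm))
      sprintf("duration ~ ASM level mixed model: beta1 = %.4f (p = %.3g); ~%.0f%% longer per unit withdrawal",
              lmm$beta1, lmm$beta1_p, percent_change(lmm$beta1, "increase")),
    if (!is.null(cat_lmm))
      sprintf("category model (ref = TES-containing): beta_tapered = %.3f, beta_typical = %.3f",
              cat_lmm$beta_tapered, cat_lmm$beta_typical),
    if (!is.null(perm))
      sprintf("TES duration permutation null: observed z = %.2f, p = %.3g",
              perm$observed, perm$p))
  writeLines(report, file.path(out_dir, "report.txt"))

  jsonlite::write_json(
    list(seed = config$seed, config = unclass(config),
         package_version = as.character(utils::packageVersion("taperstates"))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, states = states, seizures = seiz,
                 frequency = freq, freq_test = freq_test, lmm = lmm,
                 category_lmm = cat_lmm, permutation = perm))
}

#' Validate pipeline input files
#'
#' Schema and cross-file referential checks on the CSV/JSON inputs. Returns a
#' report rather than erroring, so all problems surface at once.
#'
#' @param dosing,annotations,channel_map,pk_params file paths (any may be
#'   NULL to skip).
#' @return data.frame `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(dosing = NULL, annotations = NULL,
                            channel_map = NULL, pk_params = NULL) {
  res <- list()
  add <- function(check, ok, detail = "")
    res[[length(res) + 1]] <<- data.frame(check = check, ok = ok,
                                          detail = detail)
  read_ok <- function(path, what) {
    if (!file.exists(path)) { add(paste0(what, "_exists"), FALSE, path); NULL }
    else { add(paste0(what, "_exists"), TRUE); utils::read.csv(path) }
  }
  dos <- if (!is.null(dosing)) read_ok(dosing, "dosing")
  ann <- if (!is.null(annotations)) read_ok(annotations, "annotations")
  cmap <- if (!is.null(channel_map)) read_ok(channel_map, "channel_map")
  pk <- if (!is.null(pk_params)) {
    if (!file.exists(pk_params)) { add("pk_params_exists", FALSE, pk_params); NULL }
    else { add("pk_params_exists", TRUE); jsonlite::read_json(pk_params) }
  }
  if (!is.null(dos)) {
    need <- c("subject", "drug", "dose_mg", "time_h")
    add("dosing_schema", all(need %in% names(dos)),
        paste("missing:", paste(setdiff(need, names(dos)), collapse = ",")))
    if (all(need %in% names(dos)))
      add("dosing_positive_doses", all(dos$dose_mg > 0))
  }
  if (!is.null(ann)) {
    need <- c("subject", "onset_s", "offset_s")
    add("annotations_schema", all(need %in% names(ann)),
        paste("missing:", paste(setdiff(need, names(ann)), collapse = ",")))
    if (all(need %in% names(ann))) {
      bad <- which(ann$offset_s <= ann$onset_s)
      add("annotations_offset_after_onset", length(bad) == 0,
          if (length(bad)) paste("rows:", paste(bad, collapse = ",")) else "")
    }
  }
  if (!is.null(cmap)) {
    need <- c("channel", "region")
    add("channel_map_schema", all(need %in% names(cmap)),
        paste("missing:", paste(setdiff(need, names(cmap)), collapse = ",")))
  }
  if (!is.null(dos) && !is.null(pk)) {
    missing <- setdiff(unique(dos$drug), names(pk))
    add("pk_covers_drugs", length(missing) == 0,
        paste(missing, collapse = ","))
  }
  if (!is.null(dos) && !is.null(ann)) {
    missing <- setdiff(unique(ann$subject), unique(dos$subject))
    add("dosing_covers_subjects", length(missing) == 0,
        paste(missing, collapse = ","))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
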