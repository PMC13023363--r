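# -- Dose schedules and pharmacokinetic ASM level estimation ------------------
#
# A dosing schedule (drug, dose, intake time) is converted into a continuous
# blood plasma concentration (BPC) estimate with a one-compartment first-order
# absorption/elimination model, smoothed with a 6 h moving average advanced in
# 1 h steps, normalized so the pre-taper regime fluctuates within roughly
# +/- 1 ("ASM level"), combined across drugs, and labelled by condition
# (typical / tapered / excluded).

#' Construct a dose schedule
#'
#' @param events data.frame with columns `drug` (character), `dose_mg`
#'   (positive numeric) and `time_h` (numeric hours from the recording start;
#'   may be negative for doses taken before recording onset).
#' @param pk_params named list, one entry per drug, each a list with elements
#'   `ka` (absorption rate constant, 1/h), `ke` (elimination rate constant,
#'   1/h) and `scale` (concentration units per mg; lumps bioavailability over
#'   volume of distribution, F/V).
#' @return object of class `dose_schedule`.
#' @export
dose_schedule <- function(events, pk_params) {
  stopifnot(is.data.frame(events),
            all(c("drug", "dose_mg", "time_h") %in% names(events)))
  if (nrow(events) > 0 && any(events$dose_mg <= 0))
    stop("doses must be positive")
  missing_pk <- setdiff(unique(events$drug), names(pk_params))
  if (length(missing_pk))
    stop("no PK parameters for drug(s): ", paste(missing_pk, collapse = ", "))
  for (d in names(pk_params)) {
    p <- pk_params[[d]]
    stopifnot(is.numeric(p$ka), is.numeric(p$ke), p$ka > 0, p$ke > 0)
    if (isTRUE(all.equal(p$ka, p$ke)))
      stop("ka == ke for drug ", d,
           " (limiting-form kinetics not supported; perturb one constant)")
  }
  events <- events[order(events$time_h), , drop = FALSE]
  structure(list(events = events, pk_params = pk_params),
            class = "dose_schedule")
}

#' Load per-drug pharmacokinetic parameters from JSON
#'
#' The package bundles default parameters for a few common ASMs in
#' `inst/extdata/pk_params.json`; users may edit a copy or supply their own.
#'
#' @param path path to a JSON file; default is the bundled file.
#' @return named list of per-drug PK parameter lists (`ka`, `ke`, `scale`).
#' @export
load_pk_params <- function(path = system.file("extdata", "pk_params.json",
                                              package = "taperstates")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' One-compartment plasma concentration from a dose schedule
#'
#' Superposition of single-dose curves with first-order absorption and
#' elimination: each dose i taken at t_i contributes, for t >= t_i,
#' S_i * ka/(ka - ke) * (exp(-ke (t - t_i)) - exp(-ka (t - t_i))),
#' where S_i = dose_mg * scale. Linear PK, so contributions add.
#'
#' @param schedule a [dose_schedule()].
#' @param t_grid numeric vector of hours (uniform grid, step <= 0.5 h).
#' @return data.frame `time_h` plus one concentration column per drug.
#' @export
concentration_from_schedule <- function(schedule, t_grid) {
  stopifnot(inherits(schedule, "dose_schedule"), is.numeric(t_grid),
            length(t_grid) >= 2)
  dt <- diff(t_grid)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("t_grid must be uniform")
  if (dt[1] > 0.5 + 1e-9) stop("grid step must be <= 0.5 h")
  drugs <- unique(schedule$events$drug)
  out <- data.frame(time_h = t_grid)
  for (d in drugs) {
    p <- schedule$pk_params[[d]]
    ev <- schedule$events[schedule$events$drug == d, , drop = FALSE]
    conc <- numeric(length(t_grid))
    for (i in seq_len(nrow(ev))) {
      rel <- t_grid - ev$time_h[i]
      on <- rel >= 0
      s <- ev$dose_mg[i] * p$scale
      conc[on] <- conc[on] +
        s * p$ka / (p$ka - p$ke) * (exp(-p$ke * rel[on]) - exp(-p$ka * rel[on]))
    }
    out[[d]] <- conc
  }
  out
}

#' Smooth a concentration series with a 6 h moving average
#'
#' Window means of width 6 h advanced in 1 h steps (i.e. 5 h overlap between
#' consecutive windows); output timestamps are the window centers. Smoothing
#' mitigates the unknown clock time of individual intakes.
#'
#' @param series data.frame with `time_h` and one or more value columns.
#' @param window_h,step_h window length and hop, hours.
#' @return data.frame on the coarser center grid, same value columns;
#'   attributes `window_h` and `step_h` record the smoother.
#' @export
smooth_levels <- function(series, window_h = 6, step_h = 1) {
  stopifnot(is.data.frame(series), "time_h" %in% names(series))
  t <- series$time_h
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("series grid must be uniform")
  if (max(t) - min(t) < window_h)
    stop("series shorter than the ", window_h, " h smoothing window")
  starts <- seq(min(t), max(t) - window_h, by = step_h)
  centers <- starts + window_h / 2
  vals <- setdiff(names(series), "time_h")
  out <- data.frame(time_h = centers)
  for (v in vals) {
    out[[v]] <- vapply(starts, function(s) {
      # half-open window: exactly window_h/dt samples on a uniform grid
      sel <- t >= s - 1e-9 & t < s + window_h - 1e-9
      mean(series[[v]][sel])
    }, numeric(1))
  }
  attr(out, "window_h") <- window_h
  attr(out, "step_h") <- step_h
  out
}

#' Normalize a concentration series to an ASM level
#'
#' BPCnorm = (BPC - mean(BPC over the steady interval)) /
#'           (range(BPC over the typical interval) / 2).
#'
#' The steady and typical intervals both refer to the pre-taper period of the
#' subject's usual regimen (recording start until the first taper event), so
#' the normalized level fluctuates within about +/- 1 there.
#'
#' @param series data.frame with `time_h` and a single value column (or a
#'   named column given by `col`).
#' @param steady_interval numeric length-2, hours `[from, to]` of the
#'   pre-taper steady period.
#' @param col value column to normalize (default: the first non-time column).
#' @return series with the value column replaced by its normalized version.
#' @export
normalize_level <- function(series, steady_interval, col = NULL) {
  stopifnot(is.data.frame(series), "time_h" %in% names(series),
            length(steady_interval) == 2, diff(steady_interval) > 0)
  if (is.null(col)) col <- setdiff(names(series), "time_h")[1]
  sel <- series$time_h >= steady_interval[1] - 1e-9 &
    series$time_h <= steady_interval[2] + 1e-9
  if (!any(sel)) stop("steady interval contains no samples")
  x <- series[[col]][sel]
  rng <- max(x) - min(x)
  if (rng <= 0) stop("constant concentration; normalization undefined")
  series[[col]] <- (series[[col]] - mean(x)) / (rng / 2)
  series
}

#' Combine per-drug normalized levels into one ASM level
#'
#' Pointwise mean of the per-drug normalized series, re-normalized with the
#' same steady interval so the combined typical-period level again spans 2
#' units. Averaging normalized (not raw) concentrations keeps drugs with very
#' different absolute concentrations on an equal footing.
#'
#' @param norm_series data.frame with `time_h` and one normalized column per
#'   drug.
#' @param steady_interval as in [normalize_level()].
#' @return data.frame `time_h`, `level`.
#' @export
combine_drugs <- function(norm_series, steady_interval) {
  stopifnot(is.data.frame(norm_series), "time_h" %in% names(norm_series))
  drugs <- setdiff(names(norm_series), "time_h")
  if (length(drugs) < 1) stop("no drug columns to combine")
  comb <- data.frame(time_h = norm_series$time_h,
                     level = rowMeans(norm_series[drugs]))
  normalize_level(comb, steady_interval, col = "level")
}

#' Label ASM conditions on a normalized level series
#'
#' Level in `[-1, 1]` is "typical" (the subject's usual regimen), below -1 is
#' "tapered", above +1 is "excluded" (e.g. rescue medication).
#'
#' @param series data.frame with `time_h` and `level`.
#' @return series with an added `condition` factor.
#' @export
label_conditions <- function(series) {
  stopifnot(all(c("time_h", "level") %in% names(series)))
  cond <- ifelse(series$level < -1, "tapered",
                 ifelse(series$level > 1, "excluded", "typical"))
  series$condition <- factor(cond, levels = c("typical", "tapered", "excluded"))
  series
}

#' ASM level at given times
#'
#' Linear interpolation on the smoothed, normalized series. Each seizure is
#' assigned the level at its onset time (onset exposure, duration outcome).
#'
#' @param series data.frame with `time_h` and `level`.
#' @param t_query numeric hours.
#' @return numeric levels at `t_query`.
#' @export
level_at <- function(series, t_query) {
  stopifnot(all(c("time_h", "level") %in% names(series)))
  if (any(t_query < min(series$time_h) - 1e-9 |
          t_query > max(series$time_h) + 1e-9))
    stop("query time outside the level series span")
  stats::approx(series$time_h, series$level, xout = t_query, rule = 1)$y
}

#' Full dose-schedule to ASM-level pipeline for one subject
#'
#' Concentration on a fine grid, per-drug 6 h smoothing, per-drug
#' normalization, combination across drugs, re-normalization and condition
#' labelling.
#'
#' @param schedule a [dose_schedule()].
#' @param t_span numeric length-2, hours covered by the output series.
#' @param steady_interval pre-taper interval, hours.
#' @param grid_step_h fine-grid step for the PK superposition (h).
#' @return labelled combined level series (`time_h`, `level`, `condition`)
#'   with per-drug normalized series in attribute `per_drug`.
#' @export
asm_level_series <- function(schedule, t_span, steady_interval,
                             grid_step_h = 0.25) {
  grid <- seq(t_span[1], t_span[2], by = grid_step_h)
  conc <- concentration_from_schedule(schedule, grid)
  sm <- smooth_levels(conc)
  drugs <- setdiff(names(sm), "time_h")
  for (d in drugs) sm <- normalize_level(sm, steady_interval, col = d)
  comb <- combine_drugs(sm, steady_interval)
  out <- label_conditions(comb)
  attr(out, "per_drug") <- sm
  out
}
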