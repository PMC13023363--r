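# -- Duration models and rank statistics --------------------------------------
#
# Seizure durations are analysed on the log10 scale (heavy-tailed raw
# durations). The central model is a linear mixed-effects regression of
# log10 duration on ASM level with circadian covariates and a random
# intercept per subject:
#
#   log10(dur) ~ b0 + b1*level + b2*sin(2*pi*T/24) + b3*cos(2*pi*T/24)
#                + b4*sin(2*pi*T/12) + b5*cos(2*pi*T/12) + (1 | subject)
#
# "Corrected" durations are the model residuals with the ASM-level fixed
# effect added back: subject offsets and circadian terms removed, exposure
# effect retained.

#' Validate and complete a seizure table
#'
#' @param df data.frame with at least `subject`, `onset_h` (absolute hours
#'   from recording start), `duration_s`, `asm_level`; `clock_h` (onset clock
#'   time, hours 0-24) and `log10_duration` are derived if absent.
#' @return the completed data.frame.
#' @export
as_seizure_table <- function(df) {
  need <- c("subject", "onset_h", "duration_s", "asm_level")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("seizure table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$duration_s <= 0)) stop("durations must be positive")
  if (is.null(df$clock_h)) df$clock_h <- df$onset_h %% 24
  df$log10_duration <- log10(df$duration_s)
  df
}

#' Fit the ASM-level duration mixed model
#'
#' REML fit of log10 duration on ASM level with 24 h and 12 h sine/cosine
#' covariates of onset clock time and a subject random intercept. Fixed-effect
#' p-values use Satterthwaite approximation (Wald t). Corrected durations are
#' residual + b1 * level.
#'
#' @param seizures a seizure table (see [as_seizure_table()]).
#' @param circadian include the 24/12 h sine-cosine covariates (default TRUE).
#' @return list of class `duration_lmm`: `fit` (the merMod), `coefficients`
#'   (estimate, SE, p per fixed effect), `beta1` (ASM-level slope),
#'   `corrected` (numeric vector aligned with rows of `seizures`),
#'   `residuals`, and `singular` flag.
#' @export
fit_duration_lmm <- function(seizures, circadian = TRUE) {
  seizures <- as_seizure_table(seizures)
  if (length(unique(seizures$subject)) < 2)
    stop("need at least 2 subjects for a random intercept")
  if (nrow(seizures) < 3) stop("need at least 3 seizures")
  d <- seizures
  d$sin24 <- sin(2 * pi * d$clock_h / 24)
  d$cos24 <- cos(2 * pi * d$clock_h / 24)
  d$sin12 <- sin(2 * pi * d$clock_h / 12)
  d$cos12 <- cos(2 * pi * d$clock_h / 12)
  form <- if (circadian)
    log10_duration ~ asm_level + sin24 + cos24 + sin12 + cos12 + (1 | subject)
  else
    log10_duration ~ asm_level + (1 | subject)
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit (zero between-subject variance); ",
            "estimates come from the boundary fit")
  co <- stats::coef(summary(fit))
  beta1 <- co["asm_level", "Estimate"]
  res <- stats::residuals(fit)
  structure(list(
    fit = fit,
    coefficients = co,
    beta1 = beta1,
    beta1_se = co["asm_level", "Std. Error"],
    beta1_p = co["asm_level", "Pr(>|t|)"],
    residuals = as.numeric(res),
    corrected = as.numeric(res) + beta1 * d$asm_level,
    singular = singular
  ), class = "duration_lmm")
}

#' @export
print.duration_lmm <- function(x, ...) {
  cat("Mixed model: log10 duration ~ ASM level (+ circadian) + (1|subject)\n")
  cat(sprintf("ASM-level slope b1 = %.4f (SE %.4f, p = %.3g)\n",
              x$beta1, x$beta1_se, x$beta1_p))
  invisible(x)
}

#' Fit the seizure-category duration mixed model
#'
#' log10 duration ~ category + (1 | subject), treatment coding with
#' TES-containing seizures as the reference level, fitted to subjects that
#' have taper-emergent states. Returns the tapered-without-TES and typical
#' contrasts (both expected negative when TES-containing seizures are
#' longest).
#'
#' @param seizures seizure table with a `category` column using levels
#'   `"tes"` (tapered, contains taper-emergent states), `"tapered_no_tes"`,
#'   `"typical"`.
#' @param reference reference level (default `"tes"`).
#' @return list: `fit`, `coefficients`, `beta_tapered`, `beta_typical`.
#' @export
fit_category_lmm <- function(seizures, reference = "tes") {
  seizures <- as_seizure_table(seizures)
  lev <- c("tes", "tapered_no_tes", "typical")
  present <- intersect(lev, unique(as.character(seizures$category)))
  if (length(present) < 3)
    stop("all three categories required; present: ",
         paste(present, collapse = ", "))
  seizures$category <- stats::relevel(
    factor(seizures$category, levels = lev), ref = reference)
  fit <- suppressMessages(lmerTest::lmer(
    log10_duration ~ category + (1 | subject), data = seizures, REML = TRUE))
  co <- stats::coef(summary(fit))
  pick <- function(nm) if (nm %in% rownames(co)) co[nm, "Estimate"] else NA_real_
  structure(list(
    fit = fit,
    coefficients = co,
    beta_tapered = pick("categorytapered_no_tes"),
    beta_typical = pick("categorytypical")
  ), class = "category_lmm")
}

#' Paired Wilcoxon signed-rank test with effect size r
#'
#' Signed-rank statistic on the paired differences, normal approximation
#' without continuity correction (tie-corrected variance), effect size
#' r = |z| / sqrt(n) with n the number of non-zero pairs.
#'
#' @param x,y equal-length paired numeric vectors (e.g. per-subject seizure
#'   frequency in the typical and tapered condition).
#' @param continuity apply the 0.5 continuity correction (default FALSE).
#' @return list: `statistic` (W+, sum of positive ranks), `z`, `r`, `p`
#'   (two-sided), `n`.
#' @export
wilcoxon_signed_rank_paired <- function(x, y, continuity = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need at least 5 non-zero paired differences")
  r_abs <- rank(abs(d))
  w_pos <- sum(r_abs[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r_abs)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w_pos - mu)
  if (continuity) z <- z - sign(z) * 0.5
  z <- z / sqrt(sigma2)
  list(statistic = w_pos, z = z, r = abs(z) / sqrt(n),
       p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Wilcoxon rank-sum test with effect size r
#'
#' Rank-sum z statistic (tie-corrected, no continuity correction by default);
#' effect size r = |z| / sqrt(nA + nB). The sign of `z` is positive when
#' `a` tends to exceed `b`.
#'
#' @param a,b numeric vectors.
#' @param continuity apply continuity correction (default FALSE).
#' @return list: `statistic` (rank sum of `a`), `z`, `r`, `p`, `n`.
#' @export
wilcoxon_rank_sum <- function(a, b, continuity = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r_all <- rank(c(a, b))
  w <- sum(r_all[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- table(r_all)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = w, z = 0, r = 0, p = 1, n = n))
  z <- (w - mu)
  if (continuity) z <- z - sign(z) * 0.5
  z <- z / sqrt(sigma2)
  list(statistic = w, z = z, r = abs(z) / sqrt(n),
       p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Convert a log10-duration coefficient to a percentage
#'
#' Three conventions, because relative-duration results are quoted in
#' different directions in the literature:
#' \describe{
#'   \item{remaining}{100 * 10^beta — percentage of the original duration that
#'     remains after a one-unit increase in the predictor (e.g. beta = -0.2
#'     -> 63\% remaining).}
#'   \item{increase}{100 * (10^(-beta) - 1) — percentage increase per one-unit
#'     DECREASE of the predictor (e.g. beta = -0.033 -> ~8\% longer per unit
#'     of ASM withdrawal).}
#'   \item{decrease}{100 * (1 - 10^beta) — percentage decrease per one-unit
#'     increase (e.g. beta = -0.058 -> 12.5\%).}
#' }
#'
#' @param beta coefficient in log10-duration units.
#' @param convention one of "remaining", "increase", "decrease".
#' @return percentage (numeric).
#' @export
percent_change <- function(beta,
                           convention = c("remaining", "increase", "decrease")) {
  stopifnot(is.finite(beta))
  convention <- match.arg(convention)
  switch(convention,
         remaining = 100 * 10^beta,
         increase = 100 * (10^(-beta) - 1),
         decrease = 100 * (1 - 10^beta))
}

#' Per-subject seizure frequency by ASM condition
#'
#' Count of retained seizures in each condition divided by the total time
#' (days) the subject spent in that condition. Conditions with zero observed
#' duration yield NA (missing, not zero), which paired tests then exclude.
#'
#' @param seizures seizure table with `subject` and `condition`.
#' @param condition_days data.frame `subject`, `condition`, `days` giving
#'   total days each subject spent in each condition.
#' @return data.frame `subject`, `condition`, `n_seizures`, `days`,
#'   `per_day`.
#' @export
seizure_frequency <- function(seizures, condition_days) {
  stopifnot(all(c("subject", "condition") %in% names(seizures)),
            all(c("subject", "condition", "days") %in% names(condition_days)))
  out <- condition_days
  out$n_seizures <- mapply(function(s, cc)
    sum(seizures$subject == s & seizures$condition == cc),
    out$subject, as.character(out$condition))
  out$per_day <- ifelse(out$days > 0, out$n_seizures / out$days, NA_real_)
  out
}
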