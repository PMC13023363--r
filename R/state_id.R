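# -- Seizure-state identification ---------------------------------------------
#
# Each seizure is summarized as z-scored log band power per brain region in
# six canonical bands (delta 1-4, theta 4-8, alpha 8-13, beta 13-30,
# low-gamma 30-60, high-gamma 60-100 Hz) over 5 s windows with 1 s hop,
# z-scored against the pre-ictal baseline. All of one subject's seizures are
# stacked (region x band rows) and concatenated (windows as columns) into a
# data matrix X, decomposed by non-negative matrix factorization X ~ W H.
# Columns of W are spatio-frequency patterns ("states"); rows of H are their
# per-window expression. Each window is hard-assigned to the most strongly
# expressed state, or to a null state when no expression exceeds a threshold.

#' Canonical six-band edges (Hz)
#' @export
band_edges <- function() {
  m <- rbind(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
             beta = c(13, 30), low_gamma = c(30, 60), high_gamma = c(60, 100))
  colnames(m) <- c("lo", "hi")
  m
}

# periodogram band power for a channels x samples window: one rectangular
# segment, |FFT|^2 summed over bins in [lo, hi)
window_band_power <- function(seg, fs, edges = band_edges()) {
  n <- ncol(seg)
  sp <- Mod(stats::mvfft(t(seg)))^2 / (n * fs)   # bins x channels
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sp <- sp[half, , drop = FALSE]
  freqs <- freqs[half]
  out <- matrix(0, nrow(edges), nrow(seg),
                dimnames = list(rownames(edges), rownames(seg)))
  for (b in seq_len(nrow(edges))) {
    sel <- freqs >= edges[b, 1] & freqs < edges[b, 2]
    out[b, ] <- colSums(sp[sel, , drop = FALSE])
  }
  out   # bands x channels
}

#' Region-by-band z-scored log power features for one seizure
#'
#' Sliding 5 s windows with 1 s hop anchored at the clinical onset (the last
#' partial window is dropped). Per window and channel, band power comes from
#' a one-segment periodogram integrated over the band edges, is
#' log10-transformed, then averaged over the channels in each region. Each
#' (region, band) series is z-scored against the same quantity computed on
#' the pre-ictal windows.
#'
#' @param rec a preprocessed [seizure_recording()].
#' @param channel_map data.frame `channel`, `region` covering the recording's
#'   channels.
#' @param window_s,hop_s window length and hop in seconds (defaults 5 and 1,
#'   i.e. 4 s overlap).
#' @return list of class `region_band_features`: `z` (array regions x bands x
#'   windows), `regions`, `bands`, `window_starts_s` (relative to onset),
#'   `n_windows`.
#' @export
band_power_features <- function(rec, channel_map, window_s = 5, hop_s = 1) {
  stopifnot(inherits(rec, "seizure_recording"))
  stopifnot(all(c("channel", "region") %in% names(channel_map)))
  fs <- rec$fs
  if (rec$preictal_samples < 30 * fs)
    stop("pre-ictal segment shorter than 30 s; baseline too short")
  cm <- channel_map[channel_map$channel %in% rec$channel_ids, , drop = FALSE]
  regions <- sort(unique(cm$region))
  if (!length(regions)) stop("channel map covers none of the channels")
  edges <- band_edges()
  bands <- rownames(edges)
  win <- round(window_s * fs); hop <- round(hop_s * fs)

  grid_starts <- function(from, to) {    # window fully inside [from, to]
    if (to - from + 1 < win) integer(0)
    else seq(from, to - win + 1, by = hop)
  }
  region_logpow <- function(starts) {
    out <- array(NA_real_, c(length(regions), length(bands), length(starts)))
    for (k in seq_along(starts)) {
      seg <- rec$signal[, starts[k]:(starts[k] + win - 1), drop = FALSE]
      bp <- window_band_power(seg, fs, edges)   # bands x channels
      lp <- log10(bp + .Machine$double.eps)
      for (ri in seq_along(regions)) {
        chs <- cm$channel[cm$region == regions[ri]]
        out[ri, , k] <- rowMeans(lp[, rec$channel_ids %in% chs, drop = FALSE])
      }
    }
    out
  }

  pre_starts <- grid_starts(rec$onset_sample - rec$preictal_samples,
                            rec$onset_sample - 1L)
  ict_starts <- grid_starts(rec$onset_sample, rec$offset_sample)
  if (!length(ict_starts)) stop("seizure shorter than one analysis window")
  pre <- region_logpow(pre_starts)
  ict <- region_logpow(ict_starts)

  mu <- apply(pre, c(1, 2), mean)
  sdv <- apply(pre, c(1, 2), stats::sd)
  bad <- which(sdv == 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("pre-ictal sd is zero for (region, band) = (",
         regions[bad[1, 1]], ", ", bands[bad[1, 2]], ")")
  z <- sweep(sweep(ict, c(1, 2), mu), c(1, 2), sdv, "/")
  structure(list(z = z, regions = regions, bands = bands,
                 window_starts_s = (ict_starts - rec$onset_sample) / fs,
                 n_windows = length(ict_starts)),
            class = "region_band_features")
}

#' Stack and concatenate features into the subject data matrix X
#'
#' Rows are ordered region-major, band-minor (row (r-1)*nbands + b is region
#' r, band b); columns concatenate the seizures' windows in the given order.
#' Negative z-scores are clipped at zero by default (states are defined by
#' power increases over the pre-ictal baseline); alternatively the global
#' minimum can be shifted to zero.
#'
#' @param features list of `region_band_features`, one per seizure, with
#'   identical region sets.
#' @param negatives "clip" (default) or "shift".
#' @return list: `X` ((regions*bands) x total windows, non-negative),
#'   `index` (data.frame `col`, `seizure`, `window`), `row_labels`,
#'   `regions`, `bands`.
#' @export
build_X <- function(features, negatives = c("clip", "shift")) {
  negatives <- match.arg(negatives)
  stopifnot(length(features) >= 1)
  regions <- features[[1]]$regions
  bands <- features[[1]]$bands
  for (f in features)
    if (!identical(f$regions, regions))
      stop("region sets differ across seizures")
  # region-major, band-minor: row (r-1)*nb + b  -> element z[r, b, w]
  mats <- lapply(features, function(f) {
    nr <- length(regions); nb <- length(bands); nw <- f$n_windows
    m <- matrix(NA_real_, nr * nb, nw)
    for (r in seq_len(nr))
      m[(r - 1) * nb + seq_len(nb), ] <- f$z[r, , , drop = TRUE]
    m
  })
  X <- do.call(cbind, mats)
  if (negatives == "clip") X[X < 0] <- 0
  else X <- X - min(X)
  nw <- vapply(features, function(f) f$n_windows, integer(1))
  index <- data.frame(col = seq_len(sum(nw)),
                      seizure = rep(seq_along(features), nw),
                      window = unlist(lapply(nw, seq_len)))
  row_labels <- as.vector(t(outer(regions, bands, paste, sep = ".")))
  rownames(X) <- row_labels
  list(X = X, index = index, row_labels = row_labels,
       regions = regions, bands = bands)
}

# non-negative double SVD initialization (deterministic); zero entries filled
# with the matrix mean ("nndsvda" variant) to avoid locked zeros under
# multiplicative updates
nndsvd_init <- function(X, nc) {
  sv <- svd(X, nu = nc, nv = nc)
  W <- matrix(0, nrow(X), nc); H <- matrix(0, nc, ncol(X))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (nc > 1) for (k in 2:nc) {
    u <- sv$u[, k]; v <- sv$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
    n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
    if (n_up * n_vp >= n_un * n_vn) {
      scl <- sqrt(sv$d[k] * n_up * n_vp)
      if (n_up > 0 && n_vp > 0) {
        W[, k] <- scl * up / n_up; H[k, ] <- scl * vp / n_vp
      }
    } else {
      scl <- sqrt(sv$d[k] * n_un * n_vn)
      if (n_un > 0 && n_vn > 0) {
        W[, k] <- scl * un / n_un; H[k, ] <- scl * vn / n_vn
      }
    }
  }
  eps_fill <- mean(X)
  W[W == 0] <- eps_fill * 1e-2
  H[H == 0] <- eps_fill * 1e-2
  list(W = W, H = H)
}

#' Non-negative matrix factorization of the data matrix
#'
#' Frobenius-norm NMF by multiplicative updates from a deterministic
#' non-negative double-SVD initialization. After convergence each column of W
#' is rescaled to unit maximum with the compensating scaling applied to the
#' rows of H, so state patterns are comparable across components.
#'
#' @param X non-negative matrix.
#' @param nc number of components (states), `1 <= nc <= min(dim(X))`.
#' @param seed integer; fixes the RNG for any randomized fallback so repeated
#'   calls are identical.
#' @param maxit,tol iteration cap and relative-change stopping tolerance.
#' @return list of class `state_model`: `W`, `H`, `nc`, `rel_error`
#'   (||X - WH||_F / ||X||_F), `iterations`.
#' @export
fit_nmf <- function(X, nc, seed = 1L, maxit = 10000L, tol = 1e-7) {
  stopifnot(is.matrix(X), all(X >= 0), nc >= 1)
  if (nc > min(dim(X))) stop("nc exceeds the rank bound min(dim(X))")
  set.seed(seed)
  init <- nndsvd_init(X, nc)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  nX <- sqrt(sum(X^2))
  err_prev <- Inf
  it <- 0L
  for (it in seq_len(maxit)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (tcrossprod(X, H) / (W %*% tcrossprod(H) + eps))
    if (it %% 10L == 0L || it == maxit) {
      err <- sqrt(sum((X - W %*% H)^2)) / nX
      # stop at machine-level fits or when the error curve has flattened
      # (relative improvement per 10 iterations below tol)
      if (err < 1e-13 ||
          (is.finite(err_prev) &&
             (err_prev - err) < tol * max(err_prev, 1e-300))) {
        err_prev <- err; break
      }
      err_prev <- err
    }
  }
  rel_error <- sqrt(sum((X - W %*% H)^2)) / nX
  cmax <- apply(W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(W, 2, cmax, "/")
  H <- sweep(H, 1, cmax, "*")
  structure(list(W = W, H = H, nc = nc, rel_error = rel_error,
                 iterations = it),
            class = "state_model")
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))))
}

# optimal one-to-one column matching between W1 and W2 maximizing mean cosine
# similarity; exhaustive over permutations (nc <= 7)
match_states <- function(W1, W2) {
  nc <- ncol(W1)
  stopifnot(ncol(W2) == nc, nc <= 7)
  cs <- matrix(0, nc, nc)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    d <- sqrt(sum(W1[, i]^2)) * sqrt(sum(W2[, j]^2))
    cs[i, j] <- if (d > 0) sum(W1[, i] * W2[, j]) / d else 0
  }
  pm <- permutations(nc)
  scores <- apply(pm, 1, function(p) mean(cs[cbind(seq_len(nc), p)]))
  best <- which.max(scores)
  list(perm = pm[best, ], score = scores[best],
       pair_cos = cs[cbind(seq_len(nc), pm[best, ])])
}

#' Choose the number of states
#'
#' Model-order selection by split-half stability plus the reconstruction
#' error curve: seizures are split into two halves, NMF is fitted to each,
#' and columns of the two W matrices are matched one-to-one by cosine
#' similarity. The chosen nc is the smallest candidate whose stability (mean
#' matched cosine) is at least `stability_min` and whose error curve has
#' flattened (the next component improves the relative error by less than
#' `improve_min`, or the fit is already essentially exact). An explicit
#' `override` bypasses the rule and is logged.
#'
#' @param Xb result of [build_X()].
#' @param candidates integer vector of candidate nc values.
#' @param seed RNG seed for the NMF fits.
#' @param stability_min,improve_min selection thresholds.
#' @param override optional fixed nc.
#' @return integer nc, with attributes `table` (per-candidate diagnostics)
#'   and `override` flag.
#' @export
select_nc <- function(Xb, candidates = 1:6, seed = 1L,
                      stability_min = 0.8, improve_min = 0.05,
                      override = NULL) {
  if (!is.null(override)) {
    message("select_nc: override nc = ", override)
    return(structure(as.integer(override), override = TRUE))
  }
  if (!length(candidates)) stop("empty candidate range")
  X <- Xb$X
  candidates <- candidates[candidates <= min(dim(X))]
  if (!length(candidates)) stop("no candidate within the rank bound")
  seiz <- unique(Xb$index$seizure)
  half1 <- seiz[seq_along(seiz) %% 2 == 1]
  cols1 <- Xb$index$col[Xb$index$seizure %in% half1]
  cols2 <- setdiff(Xb$index$col, cols1)
  if (!length(cols2)) { cols1 <- Xb$index$col; cols2 <- Xb$index$col }
  err <- stab <- setNames(numeric(length(candidates)), candidates)
  for (i in seq_along(candidates)) {
    nc <- candidates[i]
    err[i] <- fit_nmf(X, nc, seed = seed)$rel_error
    f1 <- fit_nmf(X[, cols1, drop = FALSE], nc, seed = seed)
    f2 <- fit_nmf(X[, cols2, drop = FALSE], nc, seed = seed)
    stab[i] <- match_states(f1$W, f2$W)$score
  }
  chosen <- NA_integer_
  for (i in seq_along(candidates)) {
    improve <- if (i < length(candidates))
      (err[i] - err[i + 1]) / max(err[i], .Machine$double.eps) else 0
    flat <- err[i] < 1e-6 || improve < improve_min
    if (stab[i] >= stability_min && flat) { chosen <- candidates[i]; break }
  }
  if (is.na(chosen)) chosen <- candidates[which.max(stab)]
  structure(as.integer(chosen), override = FALSE,
            table = data.frame(nc = candidates, rel_error = err,
                               stability = stab))
}

#' Default expression threshold
#'
#' 25th percentile of the per-window maxima of H across the subject's data
#' matrix: a subject-relative rule, scale-free in the units of H.
#'
#' @param model a `state_model`.
#' @return numeric threshold in H units.
#' @export
default_expression_threshold <- function(model) {
  stats::quantile(apply(model$H, 2, max), 0.25, names = FALSE)
}

#' Hard state assignment with a null state
#'
#' Each window takes the label of its most strongly expressed component
#' (argmax over the H column); windows whose maximum expression is below the
#' threshold get the null state, coded 0. Ties go to the lowest component
#' index.
#'
#' @param model a `state_model` from [fit_nmf()].
#' @param index column index from [build_X()].
#' @param threshold expression threshold in H units; default from
#'   [default_expression_threshold()].
#' @return list of class `state_sequences`: `labels` (integer vector per
#'   column, 0 = null), `by_seizure` (list of integer vectors), `threshold`.
#' @export
assign_states <- function(model, index, threshold = NULL) {
  stopifnot(inherits(model, "state_model"))
  if (is.null(threshold)) threshold <- default_expression_threshold(model)
  H <- model$H
  lab <- apply(H, 2, which.max)
  mx <- apply(H, 2, max)
  lab[mx < threshold] <- 0L
  lab <- as.integer(lab)
  by_seiz <- split(lab, index$seizure)
  structure(list(labels = lab, by_seizure = by_seiz, threshold = threshold),
            class = "state_sequences")
}
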