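FEATURE_NAMES <- c("apen", "energy", "lbp", "mf", "norm", "ppv", "zcr")

#' Approximate entropy parameters
#'
#' @param e embedding dimension (pattern length), integer >= 1 (default 2).
#' @param r tolerance as a multiple of the component's standard deviation
#'   (default 0.2).
#' @param norm_kind distance between embedded points: `"max"` (Chebyshev,
#'   the standard ApEn choice, default) or `"euclidean"`.
#' @return list of class `apen_params`.
#' @export
apen_params <- function(e = 2, r = 0.2, norm_kind = c("max", "euclidean")) {
  norm_kind <- match.arg(norm_kind)
  stopifnot(e >= 1, r >= 0)
  structure(list(e = as.integer(e), r = r, norm_kind = norm_kind),
            class = "apen_params")
}

#' Approximate entropy
#'
#' Two-term correlation-integral form with self-matches included
#' (Heaviside at zero counts as a match): the mean of `log C_i^e(r)` over
#' the `N-e+1` length-`e` windows minus the mean of `log C_i^(e+1)(r)` over
#' the `N-e` length-`(e+1)` windows. The tolerance is resolved as
#' `params$r * sd(x)`, which makes the statistic exactly invariant to
#' positive amplitude scaling. A constant sequence returns 0.
#'
#' @param x numeric component.
#' @param params an [apen_params()].
#' @return scalar approximate entropy (nats).
#' @export
apen <- function(x, params = apen_params()) {
  N <- length(x)
  if (N <= params$e + 1)
    stop_config("component too short for ApEn: N=", N, " <= e+1=",
                params$e + 1)
  s <- sd(x)
  if (s == 0) return(0)
  cpp_apen(as.numeric(x), params$e, params$r * s,
           params$norm_kind == "max")
}

#' Signal energy: sum of squared magnitudes
#' @param x numeric component (non-empty).
#' @return scalar `sum(x^2)`.
#' @export
energy <- function(x) {
  if (length(x) == 0) stop_config("empty component")
  sum(x^2)
}

#' Logarithmic band power: natural log of the mean squared amplitude
#'
#' An identically-zero component would have log power `-Inf`; it returns
#' the configured floor `log(1e-12)` flagged with attribute
#' `degenerate = TRUE` (placeholder IMF slots hit this path).
#'
#' @param x numeric component (non-empty).
#' @return scalar `log(mean(x^2))`.
#' @export
lbp <- function(x) {
  if (length(x) == 0) stop_config("empty component")
  p <- mean(x^2)
  if (p == 0)
    return(structure(log(1e-12), degenerate = TRUE))
  log(p)
}

#' Mean frequency of the power spectrum
#'
#' Power-weighted average frequency `sum(f * P) / sum(P)` over a
#' full-length rectangular-window periodogram (one-sided bins from 0 to
#' Nyquist inclusive). Exact for bin-aligned tones. A zero-power component
#' returns 0 flagged with attribute `degenerate = TRUE`.
#'
#' @param x numeric component.
#' @param fs sampling rate in Hz.
#' @return scalar mean frequency in Hz.
#' @export
mean_frequency <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop_config("component too short for a spectrum")
  P <- Mod(fft(as.numeric(x)))^2 / n
  half <- floor(n / 2) + 1
  f <- (seq_len(half) - 1) * fs / n
  P <- P[seq_len(half)]
  tot <- sum(P)
  if (tot == 0) return(structure(0, degenerate = TRUE))
  sum(f * P) / tot
}

#' Euclidean norm: square root of the signal energy
#' @param x numeric component (non-empty).
#' @return scalar `sqrt(sum(x^2))`.
#' @export
norm_feature <- function(x) sqrt(energy(x))

#' Peak-to-peak value: range of the component
#' @param x numeric component (non-empty).
#' @return scalar `|max(x) - min(x)|`.
#' @export
ppv <- function(x) {
  if (length(x) == 0) stop_config("empty component")
  abs(max(x) - min(x))
}

#' Zero-crossing rate
#'
#' Literal normalized sign-shift sum
#' `(1/N) * sum_{n=2}^{N} |sgn(x_n) - sgn(x_{n-1})|` with the convention
#' `sgn(x >= 0) = 1`, `sgn(x < 0) = -1`; each crossing contributes 2, so
#' the range is `[0, 2)`.
#'
#' @param x numeric component, length >= 2.
#' @return scalar zero-crossing rate.
#' @export
zcr <- function(x) {
  N <- length(x)
  if (N < 2) stop_config("need at least 2 samples for ZCR")
  s <- ifelse(x >= 0, 1, -1)
  sum(abs(diff(s))) / N
}

# evaluate one named feature on one component
eval_feature <- function(name, x, fs, params) {
  switch(name,
         apen = apen(x, params),
         energy = energy(x),
         lbp = as.numeric(lbp(x)),
         mf = as.numeric(mean_frequency(x, fs)),
         norm = norm_feature(x),
         ppv = ppv(x),
         zcr = zcr(x),
         stop_config("unknown feature: ", name))
}

#' Per-trial feature vector over all channels and components
#'
#' Evaluates one scalar feature on every component (IMF1..IMFn, residual)
#' of every channel's decomposition, in channel-major order, producing one
#' `1 x (n_channels * (n_imfs + 1))` row named `<channel>_<component>`.
#'
#' @param imfsets named list: one [emd_decompose()] result per channel, in
#'   montage order; all must share the epoch length.
#' @param feature_name one of `r paste(FEATURE_NAMES, collapse = ", ")`.
#' @param fs sampling rate in Hz (needed by `mf`).
#' @param params an [apen_params()] (used by `apen` only).
#' @return named numeric vector.
#' @export
compute_feature_vector <- function(imfsets, feature_name,
                                   fs = 200, params = apen_params()) {
  feature_name <- match.arg(feature_name, FEATURE_NAMES)
  lens <- vapply(imfsets, `[[`, 0, "n")
  if (length(unique(lens)) != 1)
    stop_config("channel decompositions have inconsistent epoch lengths")
  chn <- names(imfsets)
  if (is.null(chn)) chn <- paste0("Ch", seq_along(imfsets))
  out <- numeric(0)
  for (ci in seq_along(imfsets)) {
    comps <- imf_components(imfsets[[ci]])
    comp_names <- c(paste0("IMF", seq_len(length(comps) - 1)), "residual")
    v <- vapply(comps, function(x) eval_feature(feature_name, x, fs, params),
                numeric(1))
    names(v) <- paste0(chn[ci], "_", comp_names)
    out <- c(out, v)
  }
  out
}

#' Decompose every channel of an epoch
#'
#' @param ep an `epoch` from [epoch_signal()].
#' @param n_imfs IMF slots per channel (default 7).
#' @param stop a [sift_stop()].
#' @return named list of `imf_set`, one per channel.
#' @export
decompose_epoch <- function(ep, n_imfs = 7, stop = sift_stop()) {
  stopifnot(inherits(ep, "epoch"))
  sets <- lapply(seq_len(nrow(ep$data)),
                 function(ch) emd_decompose(ep$data[ch, ], n_imfs, stop))
  names(sets) <- rownames(ep$data)
  sets
}

#' Stack per-epoch feature vectors into a feature matrix
#'
#' @param epoch_imfsets list with one element per trial, each a list of
#'   per-channel `imf_set` objects (see [decompose_epoch()]).
#' @param epochs the matching list of `epoch` objects (labels, subject ids,
#'   sampling rates).
#' @param feature_name scalar feature to evaluate.
#' @param params an [apen_params()].
#' @return a [feature_matrix()]; row order follows the input epoch order.
#' @export
build_feature_matrix <- function(epoch_imfsets, epochs, feature_name,
                                 params = apen_params()) {
  stopifnot(length(epoch_imfsets) == length(epochs),
            length(epochs) >= 1)
  fss <- vapply(epochs, `[[`, 0, "fs")
  if (length(unique(fss)) != 1) stop_config("mixed sampling rates")
  rows <- lapply(seq_along(epochs), function(i)
    compute_feature_vector(epoch_imfsets[[i]], feature_name,
                           fs = fss[1], params = params))
  values <- do.call(rbind, rows)
  feature_matrix(values,
                 labels = vapply(epochs, `[[`, "", "class_label"),
                 subject_ids = vapply(epochs, `[[`, "", "subject_id"),
                 feature_name = feature_name)
}

#' Full front end: filter, epoch, decompose, featurize a cohort
#'
#' Runs the band-pass filter, cuts epochs, decomposes every channel epoch
#' once, then evaluates each requested feature on the shared
#' decompositions.
#'
#' @param cohort list of `eeg_recording` objects.
#' @param features character vector of feature names (default all seven).
#' @param filter_spec a [design_bandpass()] (default 0.1--60 Hz elliptic at
#'   the cohort's sampling rate); `NULL` skips filtering.
#' @param epoch_seconds trial length (default 8 s).
#' @param n_imfs IMF slots (default 7).
#' @param stop a [sift_stop()].
#' @param params an [apen_params()].
#' @param max_epochs optional per-recording epoch cap.
#' @return named list of [feature_matrix()] objects, one per feature.
#' @export
extract_features <- function(cohort, features = FEATURE_NAMES,
                             filter_spec = NULL, epoch_seconds = 8,
                             n_imfs = 7, stop = sift_stop(),
                             params = apen_params(), max_epochs = NULL) {
  features <- match.arg(features, FEATURE_NAMES, several.ok = TRUE)
  fs <- cohort[[1]]$fs
  if (is.null(filter_spec))
    filter_spec <- design_bandpass(0.1, 60, fs)
  all_epochs <- list()
  all_sets <- list()
  for (rec in cohort) {
    filtered <- if (inherits(filter_spec, "filter_spec"))
      apply_filter(rec, filter_spec) else rec
    eps <- epoch_signal(filtered, epoch_seconds, max_epochs)
    for (ep in eps) {
      all_epochs[[length(all_epochs) + 1]] <- ep
      all_sets[[length(all_sets) + 1]] <- decompose_epoch(ep, n_imfs, stop)
    }
  }
  out <- lapply(features, function(f)
    build_feature_matrix(all_sets, all_epochs, f, params))
  names(out) <- features
  out
}
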