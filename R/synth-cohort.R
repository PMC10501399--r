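#' Class-conditional spectral profile for the synthetic EEG generator
#'
#' Describes the band-power structure of one diagnostic class: relative
#' linear power weights for the four classical EEG bands (delta 0.5--4 Hz,
#' theta 4--8 Hz, alpha 8--13 Hz, beta 13--30 Hz) riding on a `1/f^beta`
#' background at a given structured-to-background SNR.
#'
#' @param class_label one of `"neurotypical"`, `"mild_ad"`, `"moderate_ad"`.
#' @param band_weights named numeric vector of nonnegative relative linear
#'   power weights; names must be `delta`, `theta`, `alpha`, `beta`; at
#'   least one weight must be positive.
#' @param background_exponent spectral slope beta of the `1/f^beta`
#'   background (dimensionless, default 1).
#' @param snr_db ratio of total structured band power to background power,
#'   in dB.
#' @return an object of class `class_spectral_profile`.
#' @export
class_spectral_profile <- function(class_label, band_weights,
                                   background_exponent = 1, snr_db = 6) {
  class_label <- match.arg(class_label, AD_CLASSES)
  if (!all(names(EEG_BANDS) %in% names(band_weights)))
    stop_config("band_weights must name all of: ",
                paste(names(EEG_BANDS), collapse = ", "))
  band_weights <- band_weights[names(EEG_BANDS)]
  if (any(band_weights < 0) || !any(band_weights > 0))
    stop_config("band_weights must be nonnegative with at least one > 0")
  structure(list(class_label = class_label,
                 band_weights = band_weights,
                 background_exponent = background_exponent,
                 snr_db = snr_db),
            class = "class_spectral_profile")
}

#' Default three-class spectral profiles
#'
#' Alpha weights 3/2/1 and theta weights 1/2/3 across
#' neurotypical / mild AD / moderate AD encode the canonical AD
#' "alpha slowing" biomarker pattern (reduced alpha, increased theta with
#' disease severity); delta and beta weights are held constant across
#' classes. `contrast` linearly interpolates each class's weights between
#' the across-class mean (`contrast = 0`, no class signal at all) and the
#' full default contrast (`contrast = 1`).
#'
#' @param contrast scalar in `[0, 1]` scaling the between-class separation.
#' @param snr_db structured-to-background SNR passed to every profile.
#' @return named list of three [class_spectral_profile()] objects.
#' @export
default_profiles <- function(contrast = 1, snr_db = 6) {
  stopifnot(contrast >= 0, contrast <= 1)
  base <- list(
    neurotypical = c(delta = 2, theta = 1, alpha = 3, beta = 0.5),
    mild_ad      = c(delta = 2, theta = 2, alpha = 2, beta = 0.5),
    moderate_ad  = c(delta = 2, theta = 3, alpha = 1, beta = 0.5))
  mean_w <- Reduce(`+`, base) / length(base)
  lapply(stats::setNames(AD_CLASSES, AD_CLASSES), function(cl) {
    w <- mean_w + contrast * (base[[cl]] - mean_w)
    class_spectral_profile(cl, w, background_exponent = 1, snr_db = snr_db)
  })
}

#' Specification of a synthetic EEG cohort
#'
#' @param subjects_per_class integer (single value recycled, or one per
#'   class); must be at least 2 per class so cross-validation is feasible.
#' @param trials_per_subject number of 8-s trials per subject (default 28,
#'   matching the per-record epoch count of the motivating acquisition
#'   protocol).
#' @param n_channels number of EEG channels (default 20).
#' @param fs sampling rate in Hz (default 200).
#' @param epoch_seconds trial duration in seconds (default 8);
#'   `fs * epoch_seconds` must be an integer.
#' @param seed integer master seed; all cohort randomness derives from it.
#' @param profiles named list of one [class_spectral_profile()] per class
#'   (default [default_profiles()]).
#' @param channel_labels montage names, length `n_channels`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(subjects_per_class = 5, trials_per_subject = 28,
                        n_channels = 20, fs = 200, epoch_seconds = 8,
                        seed = 1, profiles = default_profiles(),
                        channel_labels = NULL) {
  spc <- rep_len(as.integer(subjects_per_class), length(AD_CLASSES))
  names(spc) <- AD_CLASSES
  if (any(spc < 2))
    stop_config("invariant violated: subjects_per_class >= 2 for every ",
                "class (got ", paste(spc, collapse = "/"), ")")
  n_samp <- fs * epoch_seconds
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop_config("invariant violated: fs * epoch_seconds must be an integer ",
                "number of samples (got ", n_samp, ")")
  if (trials_per_subject < 1) stop_config("trials_per_subject must be >= 1")
  if (!all(AD_CLASSES %in% names(profiles)))
    stop_config("profiles must be named by class: ",
                paste(AD_CLASSES, collapse = ", "))
  if (is.null(channel_labels))
    channel_labels <- if (n_channels <= length(MONTAGE_1020))
      MONTAGE_1020[seq_len(n_channels)]
    else paste0("Ch", seq_len(n_channels))
  stopifnot(length(channel_labels) == n_channels)
  structure(list(subjects_per_class = spc,
                 trials_per_subject = as.integer(trials_per_subject),
                 n_channels = as.integer(n_channels), fs = fs,
                 epoch_seconds = epoch_seconds, seed = as.integer(seed),
                 profiles = profiles[AD_CLASSES],
                 channel_labels = channel_labels),
            class = "cohort_spec")
}

# one unit-power band-limited Gaussian noise epoch via FFT-domain masking
band_noise <- function(n, fs, f_lo, f_hi) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  W[f < f_lo | f >= f_hi] <- 0   # half-open band [lo, hi)
  x <- Re(fft(W, inverse = TRUE)) / n
  p <- mean(x^2)
  if (p > 0) x / sqrt(p) else x
}

# unit-power 1/f^beta background epoch
background_noise <- function(n, fs, beta) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  p <- mean(x^2)
  if (p > 0) x / sqrt(p) else x
}

# one epoch drawn from a profile with (possibly jittered) band weights
model_epoch <- function(n, fs, weights, beta, snr_db) {
  x <- numeric(n)
  for (b in names(EEG_BANDS)) {
    if (weights[[b]] <= 0) next
    rng <- EEG_BANDS[[b]]
    x <- x + sqrt(weights[[b]]) * band_noise(n, fs, rng[1], rng[2])
  }
  bg_power <- sum(weights) / 10^(snr_db / 10)
  x + sqrt(bg_power) * background_noise(n, fs, beta)
}

#' Generate a seeded synthetic EEG cohort
#'
#' Each channel epoch is a sum of band-limited Gaussian noise components
#' (FFT-domain shaping, one per EEG band, power proportional to the class
#' profile's band weight) plus a `1/f^beta` background. Subjects within a
#' class receive a seeded multiplicative jitter (+/-10%) on their band
#' weights, so subject identity carries signal and grouped cross-validation
#' is non-trivial. Channels share a 30% common-source component per trial;
#' the remaining 70% of the variance is channel-independent. The same spec
#' (including seed) reproduces the cohort bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @return list of `eeg_recording` objects (`subjects_per_class` recordings
#'   per class), each `n_channels x (trials_per_subject * fs *
#'   epoch_seconds)`, in microvolts.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_config("spec must be a cohort_spec")
  n <- round(spec$fs * spec$epoch_seconds)
  n_subj_total <- sum(spec$subjects_per_class)
  sub_seeds <- with_seed(spec$seed,
                         function() sample.int(2147483646L, n_subj_total))
  recs <- vector("list", n_subj_total)
  idx <- 0L
  rho <- 0.3                                  # common-source variance share
  amp_uv <- 10                                # nominal RMS amplitude, uV
  for (cl in AD_CLASSES) {
    prof <- spec$profiles[[cl]]
    for (s in seq_len(spec$subjects_per_class[[cl]])) {
      idx <- idx + 1L
      subject_id <- sprintf("%s_%02d", cl, s)
      data <- with_seed(sub_seeds[idx], function() {
        w <- prof$band_weights * runif(length(prof$band_weights), 0.9, 1.1)
        mat <- matrix(0, spec$n_channels, spec$trials_per_subject * n)
        for (tr in seq_len(spec$trials_per_subject)) {
          common <- model_epoch(n, spec$fs, w, prof$background_exponent,
                                prof$snr_db)
          cols <- ((tr - 1) * n + 1):(tr * n)
          for (ch in seq_len(spec$n_channels)) {
            own <- model_epoch(n, spec$fs, w, prof$background_exponent,
                               prof$snr_db)
            mat[ch, cols] <- amp_uv * (sqrt(rho) * common +
                                       sqrt(1 - rho) * own)
          }
        }
        mat
      })
      rownames(data) <- spec$channel_labels
      recs[[idx]] <- eeg_recording(subject_id, cl, spec$fs,
                                   spec$channel_labels, data)
    }
  }
  attr(recs, "cohort_spec") <- spec
  recs
}

#' Per-class mean band power of a cohort
#'
#' Averages periodogram power inside `band` over all epochs and channels of
#' each class — a sanity surface for the generator's spectral contrasts
#' (e.g. theta power should be highest for moderate AD under the default
#' profiles).
#'
#' @param cohort list of `eeg_recording` objects.
#' @param band numeric length-2 frequency range in Hz, within Nyquist.
#' @param epoch_seconds epoch length used to chop recordings for the
#'   periodogram (default 8).
#' @return named numeric vector: mean band power (uV^2/bin) per class
#'   present in the cohort.
#' @export
class_contrast_report <- function(cohort, band, epoch_seconds = 8) {
  if (length(cohort) == 0) stop_config("cohort is empty")
  stopifnot(length(band) == 2, band[1] < band[2])
  fs <- cohort[[1]]$fs
  if (band[2] > fs / 2) stop_config("band exceeds Nyquist frequency")
  classes <- unique(vapply(cohort, `[[`, "", "class_label"))
  out <- vapply(classes, function(cl) {
    tot <- 0; cnt <- 0
    for (rec in cohort) {
      if (rec$class_label != cl) next
      n <- round(fs * epoch_seconds)
      n_ep <- floor(ncol(rec$data) / n)
      for (ep in seq_len(n_ep)) {
        seg <- rec$data[, ((ep - 1) * n + 1):(ep * n), drop = FALSE]
        for (ch in seq_len(nrow(seg))) {
          P <- Mod(fft(seg[ch, ]))^2 / n
          f <- (seq_len(n) - 1) * fs / n
          sel <- f >= band[1] & f < band[2] & f <= fs / 2
          tot <- tot + mean(P[sel]); cnt <- cnt + 1
        }
      }
    }
    tot / cnt
  }, numeric(1))
  names(out) <- classes
  out
}
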