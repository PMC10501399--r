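# pair polynomial roots into conjugate pairs, largest radius first
pair_conjugates <- function(r) {
  r <- r[order(-Mod(r), Im(r))]
  used <- rep(FALSE, length(r))
  pairs <- list()
  for (i in seq_along(r)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(r[i])) > 1e-8) {
      j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
      if (is.na(j)) stop_config("unpaired complex root in filter design")
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(r[i], r[j])
    } else {
      pairs[[length(pairs) + 1]] <- r[i]
    }
  }
  pairs
}

roots_to_quad <- function(rt) {
  if (length(rt) == 2) c(1, -Re(rt[1] + rt[2]), Re(rt[1] * rt[2]))
  else if (length(rt) == 1) c(1, -Re(rt[1]), 0)
  else c(1, 0, 0)
}

#' Design an elliptic band-pass filter
#'
#' IIR elliptic (Cauer) band-pass with equiripple passband and stopband.
#' `order` is the analog prototype order; the resulting digital band-pass
#' has order `2 * order`. The direct-form design is factored into cascaded
#' second-order sections (conjugate pole/zero pairing, largest-radius poles
#' first) for numerically robust application at extreme cutoff ratios such
#' as 0.1 Hz at a 200 Hz rate.
#'
#' @param low_cut,high_cut passband edges in Hz; `0 < low_cut < high_cut <
#'   fs/2`.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 4).
#' @param ripple_db peak-to-peak passband ripple in dB (default 0.1).
#' @param atten_db minimum stopband attenuation in dB (default 40).
#' @return object of class `filter_spec` with elements `sos` (n x 6 matrix
#'   of `b0 b1 b2 a0 a1 a2` rows), `gain`, `b`, `a`, and the design
#'   parameters.
#' @export
design_bandpass <- function(low_cut, high_cut, fs, order = 4,
                            ripple_db = 0.1, atten_db = 40) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    stop_config("invalid band edges: need 0 < low_cut < high_cut < fs/2 ",
                "(got ", low_cut, ", ", high_cut, " at fs=", fs, ")")
  fl <- signal::ellip(order, ripple_db, atten_db,
                      c(low_cut, high_cut) / (fs / 2), "pass")
  z <- polyroot(rev(fl$b))
  p <- polyroot(rev(fl$a))
  if (max(Mod(p)) >= 1)
    stop_config("designed filter is unstable (pole radius ",
                max(Mod(p)), ")")
  zp <- pair_conjugates(z)
  pp <- pair_conjugates(p)
  nsec <- max(length(zp), length(pp))
  # pair each pole pair (closest to the unit circle first) with the
  # nearest unused zero pair, so no section has spurious gain
  zused <- rep(FALSE, length(zp))
  sos <- matrix(0, nsec, 6)
  for (s in seq_len(nsec)) {
    aa <- roots_to_quad(if (s <= length(pp)) pp[[s]] else complex(0))
    bb <- c(1, 0, 0)
    if (any(!zused)) {
      pref <- if (s <= length(pp)) pp[[s]][1] else 0 + 0i
      cand <- which(!zused)
      d <- vapply(cand, function(i) min(Mod(zp[[i]] - pref)), numeric(1))
      pick <- cand[which.min(d)]
      zused[pick] <- TRUE
      bb <- roots_to_quad(zp[[pick]])
    }
    sos[s, ] <- c(bb, aa)
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, fs = fs,
                 order = order, passband_ripple = ripple_db,
                 stopband_atten = atten_db,
                 sos = sos, gain = fl$b[1] / fl$a[1],
                 b = fl$b, a = fl$a),
            class = "filter_spec")
}

#' Frequency response of a designed filter
#'
#' Evaluates the SOS cascade's complex response at the given frequencies.
#'
#' @param spec a [design_bandpass()] result.
#' @param freqs frequencies in Hz.
#' @return complex response vector (same length as `freqs`).
#' @export
filter_response <- function(spec, freqs) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- exp(-1i * 2 * pi * freqs / spec$fs)
  h <- rep(spec$gain + 0i, length(freqs))
  for (s in seq_len(nrow(spec$sos))) {
    co <- spec$sos[s, ]
    h <- h * (co[1] + co[2] * w + co[3] * w^2) /
             (co[4] + co[5] * w + co[6] * w^2)
  }
  h
}

# single forward pass of the SOS cascade (compiled biquad chain), with
# steady-state initialisation at the signal's mean level
sos_filter <- function(spec, x) {
  x <- as.numeric(x)
  cpp_sos_filter(x, spec$sos, spec$gain, mean(x))
}

# zero-phase: odd-reflection pad, forward pass, reverse, forward, reverse,
# trim. Pad length 3x the digital filter order.
filtfilt_sos <- function(spec, x) {
  n <- length(x)
  pad <- min(n - 1, 3 * 2 * spec$order)
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(left, x, right)
  } else xp <- x
  y <- sos_filter(spec, xp)
  y <- rev(sos_filter(spec, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a recording (zero-phase)
#'
#' Applies the SOS cascade forward and backward (squaring the magnitude
#' response, cancelling phase) to every channel. Edges are odd-reflection
#' padded by three filter orders and trimmed afterwards.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [design_bandpass()] result with `spec$fs == rec$fs`.
#' @return filtered recording of the same shape.
#' @export
apply_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (abs(spec$fs - rec$fs) > 1e-9)
    stop_config("filter fs (", spec$fs, ") != recording fs (", rec$fs, ")")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- filtfilt_sos(spec, rec$data[ch, ])
  out
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping contiguous windows starting at sample 1; the trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_seconds window length in seconds.
#' @param max_epochs optional cap on the number of epochs returned.
#' @param strict if `TRUE` (default), a recording shorter than one epoch is
#'   an error; if `FALSE` an empty list is returned.
#' @return list of `epoch` objects (fields `subject_id`, `class_label`,
#'   `trial_index` starting at 0, `fs`, `data`).
#' @export
epoch_signal <- function(rec, epoch_seconds = 8, max_epochs = NULL,
                         strict = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- round(rec$fs * epoch_seconds)
  count <- floor(ncol(rec$data) / n)
  if (!is.null(max_epochs)) count <- min(count, max_epochs)
  if (count == 0) {
    if (strict) stop_config("recording shorter than one epoch (",
                            ncol(rec$data), " < ", n, " samples)")
    return(list())
  }
  lapply(seq_len(count) - 1L, function(tr) {
    structure(list(subject_id = rec$subject_id,
                   class_label = rec$class_label,
                   trial_index = tr, fs = rec$fs,
                   data = rec$data[, (tr * n + 1):((tr + 1) * n),
                                   drop = FALSE]),
              class = "epoch")
  })
}

#' Total-duration bookkeeping for a set of epochs
#'
#' @param epochs list of `epoch` objects, or an integer count.
#' @param epoch_seconds window length in seconds.
#' @return total duration in seconds (`count * epoch_seconds`).
#' @export
epoch_total_duration <- function(epochs, epoch_seconds = 8) {
  count <- if (is.numeric(epochs)) epochs else length(epochs)
  count * epoch_seconds
}
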