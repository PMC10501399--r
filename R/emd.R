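#' Locate interior extrema of a sequence
#'
#' Interior sample `i` is a maximum iff it exceeds both neighbouring values;
#' plateaus of equal values count once, at the plateau midpoint (rounded
#' down). Maxima and minima therefore alternate. Endpoints are never
#' extrema.
#'
#' @param x numeric sequence, length >= 3.
#' @return object of class `extrema_set`: lists `maxima`/`minima` of 1-based
#'   indices with matching `max_values`/`min_values`.
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) stop_config("sequence too short for extrema (length ",
                                 length(x), " < 3)")
  ex <- cpp_find_extrema(as.numeric(x))
  structure(list(maxima = ex$maxima + 1L, minima = ex$minima + 1L,
                 max_values = x[ex$maxima + 1L],
                 min_values = x[ex$minima + 1L]),
            class = "extrema_set")
}

#' Cubic-spline upper/lower envelopes and their mean
#'
#' Natural cubic splines through the maxima (upper) and minima (lower),
#' after mirroring the two nearest extrema of each kind about both
#' endpoints; with fewer than four knots the fit degrades to linear
#' interpolation. The mean envelope is `(upper + lower) / 2` exactly.
#'
#' @param x numeric sequence.
#' @param extrema optional [find_extrema()] result (recomputed if missing;
#'   the sifting path always recomputes internally).
#' @return object of class `envelope_pair` with `upper`, `lower`, `mean`
#'   sampled on `x`'s grid, or a condition of class `emdad_monotone` when
#'   there are fewer than two maxima or two minima.
#' @export
interpolate_envelopes <- function(x, extrema = NULL) {
  env <- cpp_envelopes(as.numeric(x))
  if (!env$ok)
    stop(structure(class = c("emdad_monotone", "error", "condition"),
                   list(message = "monotone residual: fewer than 2 maxima or 2 minima",
                        call = sys.call(-1))))
  structure(list(upper = env$upper, lower = env$lower, mean = env$mean),
            class = "envelope_pair")
}

#' One sifting step
#'
#' Subtracts the mean envelope from the working signal: `h_new = h - M`.
#'
#' @param h numeric sequence admitting envelopes.
#' @return list with `h_new` and the mean envelope `M` used.
#' @export
sift_once <- function(h) {
  env <- interpolate_envelopes(h)
  list(h_new = h - env$mean, M = env$mean)
}

#' Sifting stop criteria
#'
#' @param sd_threshold Cauchy criterion: stop when
#'   `sum((h_prev - h_new)^2) / sum(h_prev^2)` drops below this (default
#'   0.2, the classic sifting default).
#' @param max_sift hard cap on sifting iterations per IMF (default 10).
#' @return list of class `sift_stop`.
#' @export
sift_stop <- function(sd_threshold = 0.2, max_sift = 10) {
  stopifnot(sd_threshold >= 0, max_sift >= 1)
  structure(list(sd_threshold = sd_threshold, max_sift = as.integer(max_sift)),
            class = "sift_stop")
}

#' Extract a single intrinsic mode function
#'
#' Repeats [sift_once()] until the Cauchy SD criterion is met or `max_sift`
#' is reached. The result is checked against the IMF condition (extrema and
#' zero-crossing counts differ by at most one).
#'
#' @param x numeric sequence.
#' @param stop a [sift_stop()].
#' @return list with `imf`, `sift_count`, and `imf_ok` (condition check).
#'   Raises an `emdad_monotone` condition when `x` admits no envelope.
#' @export
extract_imf <- function(x, stop = sift_stop()) {
  res <- cpp_extract_imf(as.numeric(x), stop$sd_threshold, stop$max_sift)
  if (res$monotone)
    stop(structure(class = c("emdad_monotone", "error", "condition"),
                   list(message = "monotone input: no IMF can be sifted",
                        call = sys.call(-1))))
  list(imf = res$imf, sift_count = res$sift_count, imf_ok = res$imf_ok)
}

#' Empirical mode decomposition into a fixed number of IMFs plus residual
#'
#' Sifts IMFs one at a time, subtracting each from the running residual.
#' If the residual becomes monotone before `n_imfs` modes are found, the
#' remaining IMF slots are zero sequences flagged as placeholders, keeping
#' the component count (and hence downstream feature-vector width)
#' constant. The telescoping construction guarantees
#' `colSums(imfs) + residual == x` to floating-point accuracy.
#'
#' @param x finite numeric sequence (one channel epoch).
#' @param n_imfs number of IMF slots (default 7, giving 8 components with
#'   the residual).
#' @param stop a [sift_stop()].
#' @return object of class `imf_set`: `imfs` (`n_imfs` x `length(x)`
#'   matrix), `residual`, `sift_counts`, `placeholder` (logical per IMF),
#'   `condition_ok`.
#' @export
emd_decompose <- function(x, n_imfs = 7, stop = sift_stop()) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop_config("input contains non-finite values")
  res <- cpp_emd(x, as.integer(n_imfs), stop$sd_threshold, stop$max_sift)
  structure(list(imfs = res$imfs, residual = res$residual,
                 sift_counts = res$sift_counts,
                 placeholder = res$placeholder,
                 condition_ok = res$condition_ok,
                 n = length(x)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual over %d samples (%d sifted, %d placeholder)\n",
              nrow(x$imfs), x$n, sum(!x$placeholder), sum(x$placeholder)))
  invisible(x)
}

#' Components of an IMF set in feature order
#'
#' @param imfset an [emd_decompose()] result.
#' @return list of `n_imfs + 1` numeric sequences: IMF1..IMFn then the
#'   residual.
#' @export
imf_components <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  c(lapply(seq_len(nrow(imfset$imfs)), function(i) imfset$imfs[i, ]),
    list(imfset$residual))
}
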