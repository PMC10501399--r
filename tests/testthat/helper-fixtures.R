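# shared small fixtures, generated in code

fix_seed <- 20240917L

# a tiny cohort for structural tests (fast to generate)
tiny_cohort <- function(seed = fix_seed, subjects = 3, trials = 4,
                        channels = 4) {
  generate_cohort(cohort_spec(subjects_per_class = subjects,
                              trials_per_subject = trials,
                              n_channels = channels, seed = seed))
}

# sample epoch vector: mixed tones + noise, 8 s at 200 Hz
mixed_epoch <- function(seed = fix_seed, n = 1600, fs = 200) {
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 3 * t) + 0.2 * rnorm(n)
}

# brute-force oracles for the feature operators (independent of the
# package implementations)
oracle_energy <- function(x) { s <- 0; for (v in x) s <- s + abs(v)^2; s }
oracle_norm <- function(x) sqrt(oracle_energy(x))
oracle_lbp <- function(x) log(oracle_energy(x) / length(x))
oracle_ppv <- function(x) {
  mx <- x[1]; mn <- x[1]
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  abs(mx - mn)
}
oracle_zcr <- function(x) {
  sgn <- function(v) if (v >= 0) 1 else -1
  s <- 0
  for (n in 2:length(x)) s <- s + abs(sgn(x[n]) - sgn(x[n - 1]))
  s / length(x)
}
oracle_mf <- function(x, fs) {
  # direct DFT evaluation of the one-sided periodogram
  N <- length(x)
  half <- floor(N / 2) + 1
  num <- 0; den <- 0
  for (j in seq_len(half)) {
    w <- exp(-2i * pi * (j - 1) * (seq_len(N) - 1) / N)
    P <- Mod(sum(x * w))^2 / N
    f <- (j - 1) * fs / N
    num <- num + f * P; den <- den + P
  }
  num / den
}
# O(N^2) double-loop ApEn oracle, literal two-term correlation-integral
# form with self-matches; the inner j-loop is vectorised but every (i, j)
# pairwise distance is still evaluated directly
oracle_apen <- function(x, e, r_mult, chebyshev = TRUE) {
  N <- length(x)
  r <- r_mult * sd(x)
  phi <- function(m) {
    M <- N - m + 1
    emb <- sapply(seq_len(m), function(k) x[(0:(M - 1)) + k])
    if (M == 1) emb <- matrix(emb, nrow = 1)
    acc <- 0
    for (i in seq_len(M)) {
      diffs <- abs(sweep(emb, 2, emb[i, ]))
      d <- if (chebyshev) apply(diffs, 1, max)
           else sqrt(rowSums(diffs^2))
      acc <- acc + log(sum(d <= r) / M)
    }
    acc / M
  }
  phi(e) - phi(e + 1)
}

# memoised full-pipeline LBP features for the default benchmark cohort
# (5 subjects/class, 20 trials/subject, 20 channels), shared between the
# end-to-end tests
.feature_cache <- new.env(parent = emptyenv())
default_lbp_features <- function(seed, contrast = 1) {
  key <- sprintf("s%d_c%g", seed, contrast)
  if (is.null(.feature_cache[[key]])) {
    coh <- generate_cohort(cohort_spec(
      subjects_per_class = 5, trials_per_subject = 20, seed = seed,
      profiles = default_profiles(contrast = contrast)))
    .feature_cache[[key]] <- extract_features(coh, features = "lbp")
  }
  .feature_cache[[key]]
}

# periodogram band power of one epoch (independent of the generator)
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f < band[2] & f <= fs / 2
  mean(P[sel])
}
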