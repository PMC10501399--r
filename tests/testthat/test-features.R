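test_that("feature operators equal their brute-force oracles", {
  set.seed(fix_seed)
  for (rep in 1:25) {
    x <- rnorm(200)
    expect_equal(energy(x), oracle_energy(x), tolerance = 1e-12)
    expect_equal(norm_feature(x), oracle_norm(x), tolerance = 1e-12)
    expect_equal(as.numeric(lbp(x)), oracle_lbp(x), tolerance = 1e-12)
    expect_equal(ppv(x), oracle_ppv(x), tolerance = 1e-12)
    expect_equal(zcr(x), oracle_zcr(x), tolerance = 1e-12)
    expect_equal(apen(x), oracle_apen(x, 2, 0.2), tolerance = 1e-10)
  }
  x <- rnorm(400)
  expect_equal(as.numeric(mean_frequency(x, 200)), oracle_mf(x, 200),
               tolerance = 1e-9)
  # euclidean-norm ApEn variant against the same oracle
  x <- rnorm(150)
  expect_equal(apen(x, apen_params(norm_kind = "euclidean")),
               oracle_apen(x, 2, 0.2, chebyshev = FALSE),
               tolerance = 1e-10)
})

test_that("worked examples and degenerate rules hold", {
  expect_identical(energy(c(1, 2, 3)), 14)
  expect_identical(norm_feature(c(3, 4)), 5)
  expect_identical(ppv(rep(2, 5)), 0)
  expect_identical(zcr(c(1, 2, 3)), 0)
  expect_identical(zcr(c(1, -1, 1, -1)), 1.5)
  expect_identical(as.numeric(lbp(rep(1, 10))), 0)
  expect_equal(as.numeric(lbp(rep(2, 10))), log(4))
  expect_identical(apen(rep(5, 100)), 0)                 # constant
  z <- lbp(numeric(10) + 0)
  expect_identical(as.numeric(z), log(1e-12))
  expect_true(attr(z, "degenerate"))
  m <- mean_frequency(rep(0, 64), 200)
  expect_identical(as.numeric(m), 0)
  expect_true(attr(m, "degenerate"))
  expect_error(apen(rnorm(3), apen_params(e = 2)),
               class = "emdad_config_error")
})

test_that("mean frequency is exact for bin-aligned tones", {
  t <- (0:1599) / 200
  expect_equal(mean_frequency(sin(2 * pi * 10 * t), 200), 10,
               tolerance = 1e-9)
  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t)
  expect_equal(mean_frequency(two, 200), 20, tolerance = 1e-6)
})

test_that("scale covariance identities hold", {
  set.seed(fix_seed)
  x <- rnorm(300)
  c0 <- 2.7
  expect_equal(energy(c0 * x), c0^2 * energy(x))
  expect_equal(norm_feature(c0 * x), c0 * norm_feature(x))
  expect_equal(ppv(c0 * x), c0 * ppv(x))
  expect_identical(zcr(c0 * x), zcr(x))
  expect_equal(as.numeric(lbp(c0 * x)) - as.numeric(lbp(x)), 2 * log(c0))
  expect_equal(mean_frequency(c0 * x, 200), mean_frequency(x, 200))
  # SD-relative tolerance makes ApEn amplitude-scale invariant
  expect_equal(apen(c0 * x), apen(x))
  # regularity ordering: periodic square wave below white noise
  sq <- rep(c(1, -1), 100)
  expect_lt(apen(sq), apen(x[1:200]))
})

test_that("feature vectors assemble channel-major with fixed width", {
  ep <- structure(list(subject_id = "s", class_label = "mild_ad",
                       trial_index = 0L, fs = 200,
                       data = rbind(Cz = mixed_epoch(1),
                                    Pz = mixed_epoch(2))),
                  class = "epoch")
  sets <- decompose_epoch(ep)
  v <- compute_feature_vector(sets, "lbp")
  expect_length(v, 16)
  expect_identical(names(v)[1:8],
                   paste0("Cz_", c(paste0("IMF", 1:7), "residual")))
  expect_identical(names(v)[9], "Pz_IMF1")
  # placeholder components evaluate under each operator's degenerate rule
  ramp_ep <- structure(list(subject_id = "s", class_label = "mild_ad",
                            trial_index = 0L, fs = 200,
                            data = rbind(Cz = seq(0, 1, length.out = 1600))),
                       class = "epoch")
  rv <- compute_feature_vector(decompose_epoch(ramp_ep), "lbp")
  expect_identical(unname(rv[1]), log(1e-12))
})

test_that("feature matrices stack deterministically and permute with rows", {
  coh <- tiny_cohort(channels = 2)
  eps <- unlist(lapply(coh[1:2], epoch_signal, epoch_seconds = 8),
                recursive = FALSE)
  sets <- lapply(eps, decompose_epoch)
  fm <- build_feature_matrix(sets, eps, "energy")
  expect_identical(dim(fm$values), c(8L, 16L))
  expect_length(fm$labels, 8)
  # permuting the epoch order permutes rows identically
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  fm2 <- build_feature_matrix(sets[perm], eps[perm], "energy")
  expect_identical(fm2$values, fm$values[perm, ])
  expect_identical(fm2$subject_ids, fm$subject_ids[perm])
  # single epoch -> one row
  one <- build_feature_matrix(sets[1], eps[1], "zcr")
  expect_identical(nrow(one$values), 1L)
})
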