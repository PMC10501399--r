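test_that("eeg_recording validates its invariants", {
  expect_error(eeg_recording("s", "neurotypical", 200, c("A", "A"),
                             matrix(0, 2, 4)),
               "unique", class = "emdad_format_error")
  expect_error(eeg_recording("s", "neurotypical", 200, c("A", "B", "C"),
                             matrix(0, 2, 4)),
               class = "emdad_format_error")
  expect_error(eeg_recording("s", "neurotypical", -1, "A", matrix(0, 1, 4)),
               "fs", class = "emdad_format_error")
  expect_error(eeg_recording("s", "neurotypical", 200, "A",
                             matrix(c(0, NA, 1, 2), 1)),
               "finite", class = "emdad_format_error")
})

test_that("EDF round-trip stays within one quantization step", {
  set.seed(fix_seed)
  rec <- eeg_recording("subj1", "mild_ad", 200, paste0("Ch", 1:20),
                       matrix(rnorm(20 * 3200, sd = 40), 20))
  path <- file.path(tempdir(), "rt.edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path)
  expect_equal(back$fs, 200)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$class_label, "mild_ad")
  # quantization-step oracle from the stored physical/digital ranges
  for (ch in 1:20) {
    step <- (max(rec$data[ch, ]) - min(rec$data[ch, ])) / 65535
    expect_lt(max(abs(back$data[ch, ] - rec$data[ch, ])), step * 1.01)
  }
})

test_that("EDF zero signal and sampling-rate checks behave", {
  rec <- eeg_recording("z", "neurotypical", 200, c("C3", "C4"),
                       matrix(0, 2, 1600))
  path <- file.path(tempdir(), "zero.edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path, expected_fs = 200)
  expect_true(max(abs(back$data)) < (1 / 65535) * 1.01)
  expect_error(read_recording(path, expected_fs = 128),
               "mismatch", class = "emdad_format_error")
  expect_error(read_recording(file.path(tempdir(), "nope.edf")),
               class = "emdad_format_error")
})

test_that("EDF files are readable by an independent EDF implementation", {
  # cross-check the hand-written writer against Python MNE
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(fix_seed + 1)
  rec <- eeg_recording("sx", "moderate_ad", 200, c("Fp1", "Fp2"),
                       matrix(rnorm(2 * 1600, sd = 25), 2))
  path <- file.path(tempdir(), "mne.edf")
  write_recording(rec, path, "edf")
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import mne, numpy as np; raw = mne.io.read_raw_edf('", path,
    "', verbose='ERROR'); d = raw.get_data() * 1e6; ",
    "print(raw.info['sfreq'], d.shape[0], d.shape[1], ",
    "float(np.max(np.abs(d))))"))), stdout = TRUE, stderr = FALSE))
  vals <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(vals[1], 200)
  expect_equal(vals[2:3], c(2, 1600))
  expect_equal(vals[4], max(abs(rec$data)), tolerance = 1e-3)
})

test_that("text dialect round-trips bit-exactly", {
  t <- (0:99) / 200
  rec <- eeg_recording("s2", "neurotypical", 200, "Cz",
                       matrix(sin(2 * pi * 7 * t), 1))
  path <- file.path(tempdir(), "rt.tsv")
  write_recording(rec, path, "text")
  back <- read_recording(path, expected_fs = 200)
  expect_identical(back$data[1, ], unname(rec$data[1, ]))
  # 3 channels x 10 samples
  rec3 <- eeg_recording("s3", "mild_ad", 100, c("A", "B", "C"),
                        matrix(rnorm(30), 3))
  write_recording(rec3, file.path(tempdir(), "r3.tsv"), "text")
  b3 <- read_recording(file.path(tempdir(), "r3.tsv"))
  expect_identical(unname(b3$data), unname(rec3$data))
})

test_that("cohort manifest round-trips and validates files", {
  coh <- tiny_cohort()
  dir <- file.path(tempdir(), "cohortio")
  mp <- write_cohort(coh, dir, epoch_seconds = 8)
  back <- read_cohort(mp)
  expect_length(back, length(coh))
  expect_identical(vapply(back, `[[`, "", "subject_id"),
                   vapply(coh, `[[`, "", "subject_id"))
  expect_identical(vapply(back, `[[`, "", "class_label"),
                   vapply(coh, `[[`, "", "class_label"))
  # quantized but close
  expect_equal(back[[1]]$data, coh[[1]]$data, tolerance = 1e-2,
               ignore_attr = TRUE)
  # missing file detected
  file.remove(file.path(dir, jsonlite::read_json(mp)$entries[[1]]$file))
  expect_error(read_cohort(mp), "missing", class = "emdad_format_error")
})

test_that("feature matrix CSV round-trips bitwise and rejects bad shapes", {
  set.seed(fix_seed)
  vals <- matrix(rnorm(2 * 16), 2,
                 dimnames = list(NULL, paste0("Ch", rep(1:2, each = 8), "_",
                                              c(paste0("IMF", 1:7),
                                                "residual"))))
  fm <- feature_matrix(vals, c("neurotypical", "mild_ad"), c("a", "b"),
                       "lbp")
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(hdr, 18)     # 16 feature columns + 2 metadata columns
  back <- read_feature_matrix(path, "lbp")
  expect_identical(unname(back$values), unname(fm$values))  # bitwise
  expect_identical(back$labels, fm$labels)
  expect_identical(back$subject_ids, fm$subject_ids)
  # empty matrix refused on write; malformed header refused on read
  em <- feature_matrix(vals[0, , drop = FALSE], character(0), character(0))
  expect_error(write_feature_matrix(em, path),
               class = "emdad_format_error")
  writeLines("a,b\n1,2", path)
  expect_error(read_feature_matrix(path), class = "emdad_format_error")
})
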