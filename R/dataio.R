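#' Multi-channel EEG recording container
#'
#' @param subject_id character scalar.
#' @param class_label diagnostic class (`neurotypical`, `mild_ad`,
#'   `moderate_ad`) or `NA` for unlabelled data.
#' @param fs sampling rate in Hz, positive.
#' @param channel_labels unique montage names, one per data row.
#' @param data channels x samples numeric matrix in microvolts; all finite.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, class_label, fs, channel_labels, data) {
  if (!is.matrix(data)) data <- matrix(data, nrow = length(channel_labels))
  if (anyDuplicated(channel_labels))
    stop_format("channel_labels must be unique")
  if (length(channel_labels) != nrow(data))
    stop_format("channel_labels length (", length(channel_labels),
                ") != data rows (", nrow(data), ")")
  if (!is.numeric(fs) || fs <= 0) stop_format("fs must be positive")
  if (!all(is.finite(data))) stop_format("data contains non-finite samples")
  if (!is.na(class_label)) class_label <- match.arg(class_label, AD_CLASSES)
  rownames(data) <- channel_labels
  structure(list(subject_id = as.character(subject_id),
                 class_label = class_label, fs = fs,
                 channel_labels = channel_labels, data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s] %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$class_label, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# ---- EDF ----------------------------------------------------------------

# fixed-width ASCII field, right-padded
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop_format("EDF header field too wide: '", s, "'")
  formatC(s, width = -width)
}

# numeric header value that fits in 8 ASCII chars and parses back exactly
edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop_format("cannot format ", x, " in 8 chars")
}

write_edf <- function(rec, path, record_seconds = 8) {
  ns <- nrow(rec$data)
  spr <- round(rec$fs * record_seconds)
  if (ncol(rec$data) %% spr != 0)
    stop_format("sample count ", ncol(rec$data),
                " is not a whole number of ", record_seconds, "-s records")
  n_rec <- ncol(rec$data) %/% spr
  # per-channel physical range from the data; avoid a degenerate range
  pmins <- pmaxs <- character(ns)
  scale <- off <- numeric(ns)
  for (ch in seq_len(ns)) {
    lo <- min(rec$data[ch, ]); hi <- max(rec$data[ch, ])
    if (hi <= lo) hi <- lo + 1
    pmins[ch] <- edf_num(lo); pmaxs[ch] <- edf_num(hi)
    lo <- as.numeric(pmins[ch]); hi <- as.numeric(pmaxs[ch])
    scale[ch] <- (hi - lo) / 65535               # dig range -32768..32767
    off[ch] <- lo
  }
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(paste(rec$subject_id, rec$class_label), 80),
    edf_field("emdad synthetic EEG", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(record_seconds, 8), edf_field(ns, 4))
  sig <- paste0(
    paste(vapply(rec$channel_labels, edf_field, "", width = 16), collapse = ""),
    strrep(edf_field("", 80), ns),
    strrep(edf_field("uV", 8), ns),
    paste(vapply(pmins, edf_field, "", width = 8), collapse = ""),
    paste(vapply(pmaxs, edf_field, "", width = 8), collapse = ""),
    strrep(edf_field(-32768, 8), ns),
    strrep(edf_field(32767, 8), ns),
    strrep(edf_field("BP:0.1-60Hz", 80), ns),
    strrep(edf_field(spr, 8), ns),
    strrep(edf_field("", 32), ns))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  dig <- matrix(0L, ns, ncol(rec$data))
  for (ch in seq_len(ns))
    dig[ch, ] <- as.integer(pmin(32767, pmax(-32768,
      round((rec$data[ch, ] - off[ch]) / scale[ch]) - 32768)))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                        # version
  patient <- strsplit(rd(80), " +")[[1]]
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                # transducer
  for (i in seq_len(ns)) rd(8)                 # phys dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop_format("mixed samples-per-record not supported")
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- matrix(blk, nrow = ns, byrow = TRUE)
  }
  for (ch in seq_len(ns)) {
    sc <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
    data[ch, ] <- (data[ch, ] - dmin[ch]) * sc + pmin[ch]
  }
  cl <- if (length(patient) >= 2 && patient[2] %in% AD_CLASSES)
    patient[2] else NA_character_
  eeg_recording(patient[1], cl, fs, labels, data)
}

# ---- text dialect (TSV + JSON sidecar) ----------------------------------

write_text_recording <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  for (nm in names(df)) df[[nm]] <- sprintf("%.17g", df[[nm]])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  meta <- list(subject_id = rec$subject_id, class_label = rec$class_label,
               fs = rec$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_text_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_format("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- data.table::fread(path, sep = "\t", colClasses = "character",
                          data.table = FALSE)
  data <- t(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) data <- matrix(data, ncol = 1)
  eeg_recording(meta$subject_id,
                if (is.null(meta$class_label)) NA else meta$class_label,
                meta$fs, names(df), data)
}

#' Write an EEG recording to disk
#'
#' `"edf"` writes a minimal EDF file (16-bit samples, one data record per
#' `record_seconds`, per-channel physical range taken from the data);
#' round-trips are exact up to one quantization step of the stored range.
#' `"text"` writes a tab-separated table (one sample per row, channel
#' labels as header, 17 significant digits) plus a JSON metadata sidecar;
#' round-trips are bit-exact.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param format `"edf"` or `"text"`.
#' @param record_seconds EDF data-record duration (default 8 s); the
#'   recording length must be a whole number of records.
#' @export
write_recording <- function(rec, path, format = c("edf", "text"),
                            record_seconds = 8) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "edf") write_edf(rec, path, record_seconds)
  else write_text_recording(rec, path)
}

#' Read an EEG recording from disk
#'
#' Format is chosen by extension: `.edf` for EDF, anything else is the
#' package's TSV dialect with its `.json` sidecar.
#'
#' @param path file path.
#' @param expected_fs if non-`NULL`, the header sampling rate must match
#'   within 1e-6 Hz or a format error is raised.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, expected_fs = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
         else read_text_recording(path)
  if (!is.null(expected_fs) && abs(rec$fs - expected_fs) > 1e-6)
    stop_format("sampling-rate mismatch: file fs=", rec$fs,
                " Hz, expected_fs=", expected_fs, " Hz")
  rec
}

# ---- cohort manifest ----------------------------------------------------

#' Write a cohort to EDF files plus a JSON manifest
#'
#' @param cohort list of `eeg_recording` objects (e.g. from
#'   [generate_cohort()]).
#' @param dir output directory, created if needed.
#' @param epoch_seconds trial length recorded in the manifest.
#' @param format recording format, `"edf"` (default) or `"text"`.
#' @return path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, dir, epoch_seconds = 8,
                         format = c("edf", "text")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- cohort[[1]]$fs
  n <- round(fs * epoch_seconds)
  ext <- if (format == "edf") ".edf" else ".tsv"
  entries <- lapply(cohort, function(rec) {
    f <- paste0(rec$subject_id, ext)
    write_recording(rec, file.path(dir, f), format,
                    record_seconds = epoch_seconds)
    list(subject_id = rec$subject_id, class_label = rec$class_label,
         file = f, n_trials = ncol(rec$data) %/% n)
  })
  manifest <- list(fs = fs, epoch_seconds = epoch_seconds, entries = entries)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_cohort()].
#' @return list of `eeg_recording` objects, with the manifest attached as
#'   attribute `manifest`.
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  ids <- vapply(man$entries, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop_format("manifest subject_ids not unique")
  cohort <- lapply(man$entries, function(e) {
    p <- file.path(dir, e$file)
    if (!file.exists(p)) stop_format("manifest references missing file: ", p)
    rec <- read_recording(p, expected_fs = man$fs)
    rec$class_label <- e$class_label
    rec$subject_id <- e$subject_id
    rec
  })
  attr(cohort, "manifest") <- man
  cohort
}

# ---- feature matrices ---------------------------------------------------

#' Write a feature matrix to CSV
#'
#' Columns: `subject_id`, `label`, then one `<channel>_<component>` column
#' per feature value, written with 17 significant digits so parsed doubles
#' round-trip bitwise.
#'
#' @param fm a `feature_matrix` (see [build_feature_matrix()]).
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) == 0) stop_format("refusing to write an empty matrix")
  df <- data.frame(subject_id = fm$subject_ids,
                   label = as.character(fm$labels),
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(fm$values)
  for (nm in names(vals)) vals[[nm]] <- sprintf("%.17g", vals[[nm]])
  data.table::fwrite(cbind(df, vals), path, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_matrix()].
#' @param feature_name optional name to attach (CSV stores values only).
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, feature_name = NA_character_) {
  df <- data.table::fread(path, colClasses = "character",
                          data.table = FALSE)
  need <- c("subject_id", "label")
  if (!all(need %in% names(df)))
    stop_format("feature CSV must have columns: ",
                paste(need, collapse = ", "))
  if (nrow(df) == 0) stop_format("feature CSV has no rows")
  fcols <- setdiff(names(df), need)
  values <- vapply(df[fcols], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1) values <- matrix(values, nrow = 1,
                                      dimnames = list(NULL, fcols))
  feature_matrix(values, df$label, df$subject_id, feature_name)
}

#' Feature matrix container
#'
#' @param values trials x (channels x components) numeric matrix with
#'   `<channel>_<component>` column names; all values finite.
#' @param labels class label per trial.
#' @param subject_ids subject identifier per trial.
#' @param feature_name which scalar feature the values are.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subject_ids,
                           feature_name = NA_character_) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) stop_format("feature values must be finite")
  if (length(labels) != nrow(values) || length(subject_ids) != nrow(values))
    stop_format("labels/subject_ids length must equal row count")
  structure(list(values = values, labels = as.character(labels),
                 subject_ids = as.character(subject_ids),
                 feature_name = feature_name),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d trials x %d columns, %d subjects\n",
              x$feature_name, nrow(x$values), ncol(x$values),
              length(unique(x$subject_ids))))
  invisible(x)
}
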