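# z-score columns on training statistics only (no leakage); constant
# columns get unit scale
standardize_fold <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sg <- apply(train_x, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sg, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sg, "/"))
}

#' Evaluate classifier configurations on one classification issue
#'
#' For every (feature, classifier, CV scheme) cell: restrict the feature
#' matrix to the issue's classes, plan the split, then per fold z-score on
#' the training rows, fit, predict, and score. Per-fold metrics are
#' averaged unweighted into one record. Degenerate folds (single-class
#' training sets) are skipped and counted.
#'
#' @param features named list of [feature_matrix()] objects (e.g. from
#'   [extract_features()]), or a single feature matrix.
#' @param issue one of `"I".."V"` (see [make_issue_dataset()]).
#' @param configs list of [classifier_config()] objects (or a single one).
#' @param schemes character subset of `c("kfold", "loso")`.
#' @param seed integer seed for the CV shuffles.
#' @param k folds for the kfold scheme (default 10).
#' @param holdout_fraction LOSO per-class holdout fraction (default 0.2).
#' @param n_components components per channel for the sequence/map
#'   reshaping (default 8).
#' @return data.frame of evaluation records: one row per (issue, feature,
#'   classifier, scheme) with percent `precision`, `recall`, `accuracy`
#'   averaged over folds, `n_folds`, `n_skipped`, plus a `fold_metrics`
#'   list-column of the raw per-fold values.
#' @export
run_issue <- function(features, issue, configs, schemes = c("kfold", "loso"),
                      seed = 1, k = 10, holdout_fraction = 0.2,
                      n_components = 8) {
  if (inherits(features, "feature_matrix"))
    features <- stats::setNames(list(features), features$feature_name)
  if (inherits(configs, "classifier_config")) configs <- list(configs)
  schemes <- match.arg(schemes, several.ok = TRUE)
  records <- list()
  for (fname in names(features)) {
    ds <- make_issue_dataset(features[[fname]], issue)
    for (scheme in schemes) {
      plan <- plan_cv(ds$fm, scheme, k = k, seed = seed,
                      holdout_fraction = holdout_fraction)
      for (config in configs) {
        per_fold <- list(); skipped <- 0L
        for (sp in plan$splits) {
          std <- standardize_fold(
            ds$fm$values[sp$train, , drop = FALSE],
            ds$fm$values[sp$test, , drop = FALSE])
          pred <- tryCatch(
            fit_predict(config, std$train, ds$fm$labels[sp$train],
                        std$test, n_components = n_components),
            emdad_fold_skip = function(e) NULL)
          if (is.null(pred)) { skipped <- skipped + 1L; next }
          per_fold[[length(per_fold) + 1]] <-
            score(ds$fm$labels[sp$test], pred, ds$positive_class)
        }
        if (length(per_fold) == 0)
          stop_config("all folds degenerate for issue ", issue)
        rec <- data.frame(
          issue = issue, feature = fname, classifier = config$kind,
          scheme = scheme,
          precision = mean(vapply(per_fold, `[[`, 0, "precision")),
          recall = mean(vapply(per_fold, `[[`, 0, "recall")),
          accuracy = mean(vapply(per_fold, `[[`, 0, "accuracy")),
          n_folds = length(per_fold), n_skipped = skipped,
          stringsAsFactors = FALSE)
        rec$fold_metrics <- list(per_fold)
        records[[length(records) + 1]] <- rec
      }
    }
  }
  do.call(rbind, records)
}

#' Run several issues over a cohort's feature matrices
#'
#' @param features named list of feature matrices (see
#'   [extract_features()]).
#' @param issues character subset of `"I".."V"`.
#' @inheritParams run_issue
#' @return row-bound evaluation records for all issues.
#' @export
run_issues <- function(features, issues = ISSUES, configs,
                       schemes = c("kfold", "loso"), seed = 1, k = 10,
                       holdout_fraction = 0.2, n_components = 8) {
  issues <- match.arg(issues, ISSUES, several.ok = TRUE)
  do.call(rbind, lapply(issues, function(is)
    run_issue(features, is, configs, schemes, seed, k,
              holdout_fraction, n_components)))
}

#' Lay evaluation records out as result tables
#'
#' One wide table per (issue, scheme): rows are features, and each
#' classifier contributes a `Pre`/`Rec`/`Acc` column triplet (percent,
#' 1 decimal). A `best` summary lists the top-accuracy feature/classifier
#' cell per (issue, scheme).
#'
#' @param records data.frame from [run_issue()]/[run_issues()].
#' @param dir optional directory; when given, each table is written as
#'   `issue_<issue>_<scheme>.csv` plus `best_combinations.csv`.
#' @return list with `tables` (named list of data.frames) and `best`
#'   (data.frame).
#' @export
report <- function(records, dir = NULL) {
  tables <- list()
  best <- list()
  if (!is.null(records) && nrow(records) > 0) {
    for (issue in unique(records$issue)) for (sch in unique(records$scheme)) {
      sub <- records[records$issue == issue & records$scheme == sch, ]
      if (nrow(sub) == 0) next
      feats <- unique(sub$feature)
      tab <- data.frame(feature = feats, stringsAsFactors = FALSE)
      for (clf in unique(sub$classifier)) {
        m <- sub[sub$classifier == clf, ]
        m <- m[match(feats, m$feature), ]
        tab[[paste0(clf, "_Pre")]] <- round(m$precision, 1)
        tab[[paste0(clf, "_Rec")]] <- round(m$recall, 1)
        tab[[paste0(clf, "_Acc")]] <- round(m$accuracy, 1)
      }
      tables[[paste0(issue, "_", sch)]] <- tab
      top <- sub[which.max(sub$accuracy), ]
      best[[length(best) + 1]] <- data.frame(
        issue = issue, scheme = sch, feature = top$feature,
        classifier = top$classifier, accuracy = round(top$accuracy, 1),
        stringsAsFactors = FALSE)
    }
  }
  best <- if (length(best)) do.call(rbind, best)
          else data.frame(issue = character(0), scheme = character(0),
                          feature = character(0), classifier = character(0),
                          accuracy = numeric(0))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      data.table::fwrite(tables[[nm]],
                         file.path(dir, paste0("issue_", nm, ".csv")))
    data.table::fwrite(best, file.path(dir, "best_combinations.csv"))
  }
  list(tables = tables, best = best)
}
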