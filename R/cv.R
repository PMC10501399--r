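ISSUES <- c("I", "II", "III", "IV", "V")

#' Restrict and relabel a feature matrix for one classification issue
#'
#' The five diagnostic problems:
#' \describe{
#'   \item{I}{neurotypical vs mild AD (2-class; moderate trials dropped).}
#'   \item{II}{neurotypical vs moderate AD (2-class).}
#'   \item{III}{mild vs moderate AD (2-class).}
#'   \item{IV}{neurotypical vs all AD (mild and moderate merged into one
#'     positive class `ad`).}
#'   \item{V}{all three classes (3-class).}
#' }
#'
#' @param fm a [feature_matrix()] with labels in the three-class scheme.
#' @param issue one of `"I".."V"`.
#' @return list: `fm` (restricted/relabelled feature matrix),
#'   `positive_class` (the AD-side class for the binary issues, `NULL` for
#'   issue V), `label_map` (original -> issue label).
#' @export
make_issue_dataset <- function(fm, issue = ISSUES) {
  issue <- match.arg(issue)
  stopifnot(inherits(fm, "feature_matrix"))
  keep_map <- switch(issue,
    I   = c(neurotypical = "neurotypical", mild_ad = "mild_ad"),
    II  = c(neurotypical = "neurotypical", moderate_ad = "moderate_ad"),
    III = c(mild_ad = "mild_ad", moderate_ad = "moderate_ad"),
    IV  = c(neurotypical = "neurotypical", mild_ad = "ad",
            moderate_ad = "ad"),
    V   = c(neurotypical = "neurotypical", mild_ad = "mild_ad",
            moderate_ad = "moderate_ad"))
  missing <- setdiff(names(keep_map), unique(fm$labels))
  if (length(missing))
    stop_config("issue ", issue, " requires class(es) absent from the ",
                "cohort: ", paste(missing, collapse = ", "))
  sel <- fm$labels %in% names(keep_map)
  new_labels <- unname(keep_map[fm$labels[sel]])
  out <- feature_matrix(fm$values[sel, , drop = FALSE], new_labels,
                        fm$subject_ids[sel], fm$feature_name)
  positive <- switch(issue, I = "mild_ad", II = "moderate_ad",
                     III = "moderate_ad", IV = "ad", V = NULL)
  list(fm = out, positive_class = positive, label_map = keep_map)
}

#' Plan a cross-validation split
#'
#' `"kfold"` produces a class-stratified k-fold partition of trials whose
#' fold sizes differ by at most one overall (trials of every class are
#' dealt to the currently smallest folds). `"loso"` partitions subjects:
#' each split holds out as close to `holdout_fraction` of each class's
#' subjects as rounding allows, and no subject's trials ever appear on both
#' sides of a split.
#'
#' @param fm a [feature_matrix()].
#' @param scheme `"kfold"` or `"loso"`.
#' @param k number of folds for `kfold` (default 10).
#' @param seed integer seed for the shuffles.
#' @param holdout_fraction fraction of each class's subjects held out per
#'   LOSO split (default 0.2, i.e. grouped 5-fold; `1/n_subjects`
#'   approximates literal leave-one-subject-out).
#' @return object of class `cv_plan`: list of splits, each with integer
#'   `train` and `test` row indices.
#' @export
plan_cv <- function(fm, scheme = c("kfold", "loso"), k = 10, seed = 1,
                    holdout_fraction = 0.2) {
  scheme <- match.arg(scheme)
  n <- nrow(fm$values)
  if (scheme == "kfold") {
    if (n < k) stop_config("fewer trials (", n, ") than folds (", k, ")")
    fold_of <- integer(n)
    fill <- integer(k)
    with_seed(seed, function() {
      for (cl in unique(fm$labels)) {
        idx <- sample(which(fm$labels == cl))
        for (i in idx) {
          f <- which.min(fill + stats::runif(k, 0, 1e-9))  # tie-break
          fold_of[i] <<- f
          fill[f] <<- fill[f] + 1L
        }
      }
    })
    splits <- lapply(seq_len(k), function(f)
      list(train = which(fold_of != f), test = which(fold_of == f)))
  } else {
    n_folds <- max(2L, round(1 / holdout_fraction))
    subj_class <- unique(data.frame(subject = fm$subject_ids,
                                    class = fm$labels,
                                    stringsAsFactors = FALSE))
    counts <- table(subj_class$class)
    if (any(counts < n_folds))
      stop_config("loso infeasible: class '",
                  names(counts)[which.min(counts)], "' has ",
                  min(counts), " subjects but ", n_folds,
                  " splits are required")
    group_of <- stats::setNames(integer(nrow(subj_class)),
                                subj_class$subject)
    with_seed(seed, function() {
      for (cl in unique(subj_class$class)) {
        subj <- sample(subj_class$subject[subj_class$class == cl])
        group_of[subj] <<- rep_len(seq_len(n_folds), length(subj))
      }
    })
    splits <- lapply(seq_len(n_folds), function(g) {
      test_subj <- names(group_of)[group_of == g]
      list(train = which(!(fm$subject_ids %in% test_subj)),
           test = which(fm$subject_ids %in% test_subj))
    })
  }
  structure(list(scheme = scheme,
                 k = if (scheme == "kfold") k else length(splits),
                 holdout_fraction = if (scheme == "loso") holdout_fraction
                                    else NA_real_,
                 seed = seed, splits = splits),
            class = "cv_plan")
}

#' Confusion counts and precision/recall/accuracy
#'
#' Binary problems (with `positive_class` given) use the direct
#' definitions: precision `TP/(TP+FP) * 100`, recall `TP/(TP+FN) * 100`,
#' accuracy `(TP+TN)/total * 100`. Multi-class problems report
#' macro-averaged one-vs-rest precision and recall and overall accuracy
#' (confusion-matrix trace over total). An undefined precision
#' (no positive predictions) counts as 0 and sets `flagged`.
#'
#' @param truth,pred equal-length label vectors.
#' @param positive_class the positive class for binary scoring, or `NULL`
#'   for macro-averaged multi-class scoring.
#' @return list with `counts` (confusion matrix), `precision`, `recall`,
#'   `accuracy` (percent), and `flagged`.
#' @export
score <- function(truth, pred, positive_class = NULL) {
  stopifnot(length(truth) == length(pred))
  truth <- as.character(truth); pred <- as.character(pred)
  levels <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels), factor(pred, levels))
  n <- length(truth)
  flagged <- FALSE
  if (!is.null(positive_class)) {
    tp <- sum(truth == positive_class & pred == positive_class)
    fp <- sum(truth != positive_class & pred == positive_class)
    fn <- sum(truth == positive_class & pred != positive_class)
    tn <- n - tp - fp - fn
    if (tp + fp == 0) { precision <- 0; flagged <- TRUE }
    else precision <- tp / (tp + fp) * 100
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn) * 100
    accuracy <- (tp + tn) / n * 100
    counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  } else {
    prec <- rec <- numeric(length(levels))
    for (i in seq_along(levels)) {
      cl <- levels[i]
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      if (tp + fp == 0) { prec[i] <- 0; flagged <- TRUE }
      else prec[i] <- tp / (tp + fp) * 100
      rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn) * 100
    }
    precision <- mean(prec); recall <- mean(rec)
    accuracy <- sum(diag(cm)) / n * 100
    counts <- cm
  }
  list(counts = counts, precision = precision, recall = recall,
       accuracy = accuracy, flagged = flagged)
}
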