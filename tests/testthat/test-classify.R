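# two well-separated Gaussian blobs as a feature matrix; 8 columns per
# "channel" so the rnn/cnn reshaping applies
blob_fm <- function(n_per = 30, p = 16, sep = 6, seed = fix_seed,
                    classes = c("neurotypical", "mild_ad")) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = sep), n_per))
  colnames(X) <- paste0("Ch", rep(seq_len(p / 8), each = 8), "_",
                        c(paste0("IMF", 1:7), "residual"))
  labs <- rep(classes, each = n_per)
  subj <- paste0(labs, "_", rep(rep(1:5, length.out = n_per), 2))
  feature_matrix(X, labs, subj, "lbp")
}

test_that("issue datasets restrict and relabel correctly", {
  fm <- feature_matrix(matrix(rnorm(24 * 8), 24,
                              dimnames = list(NULL, paste0("Cz_",
                                c(paste0("IMF", 1:7), "residual")))),
                       rep(c("neurotypical", "mild_ad", "moderate_ad"),
                           c(10, 8, 6)),
                       paste0("s", 1:24), "lbp")
  i1 <- make_issue_dataset(fm, "I")
  expect_identical(sort(unique(i1$fm$labels)),
                   c("mild_ad", "neurotypical"))
  expect_identical(nrow(i1$fm$values), 18L)        # moderate excluded
  i4 <- make_issue_dataset(fm, "IV")
  expect_identical(sum(i4$fm$labels == "ad"), 14L) # 8 + 6 merged
  expect_identical(sum(i4$fm$labels == "neurotypical"), 10L)
  expect_identical(i4$positive_class, "ad")
  i5 <- make_issue_dataset(fm, "V")
  expect_identical(nrow(i5$fm$values), 24L)
  expect_null(i5$positive_class)
  # missing class detected
  sub <- feature_matrix(fm$values[1:10, ], fm$labels[1:10],
                        fm$subject_ids[1:10])
  expect_error(make_issue_dataset(sub, "III"), "absent",
               class = "emdad_config_error")
})

test_that("k-fold plans partition trials with imbalance <= 1", {
  fm <- blob_fm(50)
  for (seed in c(1, 7, 99)) {
    plan <- plan_cv(fm, "kfold", k = 10, seed = seed)
    tests <- unlist(lapply(plan$splits, `[[`, "test"))
    expect_identical(sort(tests), seq_len(100))            # partition
    sizes <- lengths(lapply(plan$splits, `[[`, "test"))
    expect_lte(max(sizes) - min(sizes), 1)
    for (sp in plan$splits)
      expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_identical(plan_cv(fm, "kfold", seed = 5),
                   plan_cv(fm, "kfold", seed = 5))          # deterministic
  expect_error(plan_cv(blob_fm(3), "kfold", k = 10),
               class = "emdad_config_error")
})

test_that("grouped LOSO plans never leak subjects", {
  fm <- blob_fm(30)                       # 5 subjects per class, 6 trials
  plan <- plan_cv(fm, "loso", seed = 4)
  expect_length(plan$splits, 5)           # 20% holdout -> 5 splits
  for (sp in plan$splits) {
    tr_subj <- unique(fm$subject_ids[sp$train])
    te_subj <- unique(fm$subject_ids[sp$test])
    expect_length(intersect(tr_subj, te_subj), 0)
    # one subject per class held out (20% of 5)
    te_cls <- unique(fm$labels[sp$test])
    expect_identical(sort(te_cls), sort(unique(fm$labels)))
    for (cl in te_cls)
      expect_length(unique(fm$subject_ids[sp$test][
        fm$labels[sp$test] == cl]), 1)
  }
  tests <- unlist(lapply(plan$splits, `[[`, "test"))
  expect_identical(sort(tests), seq_len(nrow(fm$values)))
  # infeasible: 3 subjects per class cannot give 5 grouped splits
  small <- blob_fm(12)
  small$subject_ids <- paste0(small$labels, "_",
                              rep(rep(1:3, length.out = 12), 2))
  expect_error(plan_cv(small, "loso"), "loso infeasible",
               class = "emdad_config_error")
})

test_that("score reproduces the binary metric formulas", {
  # TP=9 FP=1 TN=8 FN=2
  truth <- rep(c("ad", "neurotypical"), c(11, 9))
  pred <- c(rep("ad", 9), rep("neurotypical", 2),
            "ad", rep("neurotypical", 8))
  s <- score(truth, pred, positive_class = "ad")
  expect_equal(s$precision, 90)
  expect_equal(s$recall, 9 / 11 * 100)
  expect_equal(s$accuracy, 85)
  expect_identical(s$counts[["TP"]], 9L)
  # perfect prediction
  sp <- score(truth, truth, positive_class = "ad")
  expect_equal(c(sp$precision, sp$recall, sp$accuracy), c(100, 100, 100))
  # all-one-class prediction on balanced data
  bal <- rep(c("a", "b"), 10)
  sa <- score(bal, rep("a", 20), positive_class = "b")
  expect_equal(sa$accuracy, 50)
  expect_equal(sa$recall, 0)
  expect_true(sa$flagged)                     # no positive predictions
  # macro multi-class: perfect -> 100 everywhere
  m <- score(rep(c("a", "b", "c"), 5), rep(c("a", "b", "c"), 5))
  expect_equal(c(m$precision, m$recall, m$accuracy), c(100, 100, 100))
})

test_that("classifier configs carry their defaults", {
  cfg <- classifier_config("adaboost_tree")
  expect_identical(cfg$hyperparameters$n_learners, 100)
  expect_identical(cfg$hyperparameters$learning_rate, 0.01)
  ann <- classifier_config("ann")
  expect_identical(ann$hyperparameters$hidden, 10)
  expect_identical(ann$hyperparameters$epochs, 100)
  cnn <- classifier_config("cnn", dropout = 0.5)
  expect_identical(cnn$hyperparameters$dropout, 0.5)
  expect_identical(cnn$hyperparameters$filters, 96)
  expect_error(classifier_config("forest"))
})

test_that("lda separates well-separated blobs perfectly", {
  fm <- blob_fm(25, sep = 6)
  tr <- c(1:20, 26:45); te <- c(21:25, 46:50)
  pred <- fit_predict(classifier_config("lda"), fm$values[tr, ],
                      fm$labels[tr], fm$values[te, ])
  expect_identical(pred, fm$labels[te])
  # agreement with the classical discriminant when well-conditioned
  skip_if_not_installed("MASS")
  fit <- MASS::lda(fm$values[tr, ], grouping = factor(fm$labels[tr]))
  expect_identical(pred,
                   as.character(predict(fit, fm$values[te, ])$class))
})

test_that("classifiers are deterministic and permutation invariant", {
  fm <- blob_fm(25, sep = 6)
  tr <- c(1:20, 26:45); te <- c(21:25, 46:50)
  perm <- sample(seq_along(tr))
  for (kind in c("lda", "svm")) {
    cfg <- classifier_config(kind, seed = 5)
    p1 <- fit_predict(cfg, fm$values[tr, ], fm$labels[tr], fm$values[te, ])
    p2 <- fit_predict(cfg, fm$values[tr[perm], ], fm$labels[tr[perm]],
                      fm$values[te, ])
    expect_identical(p1, p2)
    expect_identical(p1, fm$labels[te])
  }
  # stochastic learners: identical given the same seed
  for (kind in c("adaboost_tree", "ann", "rnn")) {
    cfg <- classifier_config(kind, seed = 5)
    p1 <- fit_predict(cfg, fm$values[tr, ], fm$labels[tr], fm$values[te, ])
    p2 <- fit_predict(cfg, fm$values[tr, ], fm$labels[tr], fm$values[te, ])
    expect_identical(p1, p2)
  }
})

test_that("all six classifier kinds learn an easy problem", {
  fm <- blob_fm(40, sep = 6)
  tr <- c(1:32, 41:72); te <- c(33:40, 73:80)
  std <- list(train = scale(fm$values[tr, ]),
              test = scale(fm$values[te, ],
                           center = colMeans(fm$values[tr, ]),
                           scale = apply(fm$values[tr, ], 2, sd)))
  for (kind in c("lda", "svm", "adaboost_tree", "ann", "rnn", "cnn")) {
    cfg <- classifier_config(kind, seed = 3)
    pred <- fit_predict(cfg, std$train, fm$labels[tr], std$test)
    acc <- mean(pred == fm$labels[te])
    expect_gte(acc, 0.75)
  }
})

test_that("degenerate single-class training folds are signalled", {
  fm <- blob_fm(10)
  expect_error(fit_predict(classifier_config("lda"), fm$values[1:10, ],
                           fm$labels[1:10], fm$values[11:12, ]),
               class = "emdad_fold_skip")
})

test_that("run_issue produces one averaged record per cell", {
  fm <- blob_fm(30)
  recs <- run_issue(list(lbp = fm), "I",
                    list(classifier_config("lda"),
                         classifier_config("svm")),
                    schemes = c("kfold", "loso"), seed = 9)
  expect_identical(nrow(recs), 4L)         # 1 feature x 2 clf x 2 schemes
  expect_true(all(recs$accuracy >= 0 & recs$accuracy <= 100))
  # averages equal the mean of per-fold values
  for (i in seq_len(nrow(recs))) {
    folds <- recs$fold_metrics[[i]]
    expect_equal(recs$accuracy[i],
                 mean(vapply(folds, `[[`, 0, "accuracy")), tolerance = 1e-9)
    expect_equal(recs$precision[i],
                 mean(vapply(folds, `[[`, 0, "precision")),
                 tolerance = 1e-9)
  }
  # rerun with the same seed is identical
  recs2 <- run_issue(list(lbp = fm), "I",
                     list(classifier_config("lda"),
                          classifier_config("svm")),
                     schemes = c("kfold", "loso"), seed = 9)
  expect_identical(recs$accuracy, recs2$accuracy)
})

test_that("report lays records out as feature x classifier tables", {
  fm <- blob_fm(30)
  recs <- run_issue(list(lbp = fm, energy = fm), "I",
                    classifier_config("lda"), schemes = "kfold", seed = 2)
  out <- report(recs)
  tab <- out$tables[["I_kfold"]]
  expect_identical(tab$feature, c("lbp", "energy"))
  expect_identical(names(tab), c("feature", "lda_Pre", "lda_Rec",
                                 "lda_Acc"))
  expect_identical(nrow(out$best), 1L)
  # empty records -> header-only summary
  empty <- report(recs[0, ])
  expect_identical(nrow(empty$best), 0L)
  # round-trip through disk
  dir <- file.path(tempdir(), "reports")
  report(recs, dir)
  back <- data.table::fread(file.path(dir, "issue_I_kfold.csv"),
                            data.table = FALSE)
  expect_equal(back$lda_Acc, tab$lda_Acc)
})
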