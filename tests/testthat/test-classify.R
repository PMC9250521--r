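fast_svm <- function(seed = 42) model_spec("svm", cost = c(1, 10),
                                           gamma = c(1 / 184, 0.01),
                                           seed = seed)

test_that("confusion counts match the defining tallies", {
  cm <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  expect_error(confusion_counts(integer(0), integer(0)), "empty")
  expect_error(confusion_counts(c(1, 0), c(1)), "differ")
})

test_that("metric suite matches hand-derived confusion arithmetic", {
  m <- classification_metrics(confusion_counts(
    c(rep(1, 55), rep(0, 50)),
    c(rep(1, 50), rep(0, 5), rep(1, 10), rep(0, 40))))
  expect_equal(m$acc, 90 / 105, tolerance = 1e-12)
  expect_equal(m$pre, 50 / 60, tolerance = 1e-12)
  expect_equal(m$sen, 50 / 55, tolerance = 1e-12)
  expect_equal(m$spe, 40 / 50, tolerance = 1e-12)
  expect_equal(m$mcc, 1950 / sqrt(55 * 50 * 60 * 45), tolerance = 1e-12)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55),
               tolerance = 1e-12)
  # balanced symmetric confusion: MCC 0, accuracy 1/2
  sym <- classification_metrics(structure(
    list(tp = 25L, fp = 25L, tn = 25L, fn = 25L), class = "nvdt_confusion"))
  expect_equal(sym$mcc, 0)
  expect_equal(sym$acc, 0.5)
})

test_that("metric suite agrees with the brute-force oracle on random confusion matrices", {
  set.seed(31)
  for (rep in 1:500) {
    cts <- sample(0:60, 4, replace = TRUE)
    if (sum(cts) == 0) cts <- c(1, 1, 1, 1)
    cm <- structure(list(tp = cts[1], fp = cts[2], tn = cts[3], fn = cts[4]),
                    class = "nvdt_confusion")
    m <- classification_metrics(cm)
    o <- brute_metrics(cts[1], cts[2], cts[3], cts[4])
    for (k in names(o)) expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("zero-denominator metrics report 0 with a flag", {
  m <- classification_metrics(confusion_counts(c(0, 0), c(0, 0)))
  expect_equal(m$pre, 0)
  expect_equal(m$sen, 0)
  expect_true(all(c("pre", "sen", "mcc", "f1") %in% m$undefined))
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise-ordering statistic", {
  set.seed(32)
  for (rep in 1:40) {
    n <- sample(6:40, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # coarse rounding => ties
    expect_equal(auc_score(scores, y), mw_auc(scores, y), tolerance = 1e-12)
  }
  # perfectly separated scores
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_true(is.na(auc_score(c(0.5, 0.6), c(1, 1))))
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- sample(0:1, 80, replace = TRUE, prob = c(0.4, 0.6))
  y[1:2] <- c(0, 1)
  s <- round(runif(80), 2)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("training on a separable toy set is perfect and deterministic", {
  blobs <- make_blobs()
  spec <- model_spec("svm", cost = c(1, 10), gamma = c(0.05, 0.2), seed = 42)
  m1 <- train_classifier(blobs$x, blobs$y, spec)
  expect_equal(predict_classifier(m1, blobs$x)$label, blobs$y)
  m2 <- train_classifier(blobs$x, blobs$y, spec)
  expect_identical(m1$chosen, m2$chosen)
  expect_identical(predict_classifier(m1, blobs$x)$score,
                   predict_classifier(m2, blobs$x)$score)
  # rf route
  rf <- train_classifier(blobs$x, blobs$y,
                         model_spec("rf", n_tree = c(50, 100), seed = 42))
  expect_equal(predict_classifier(rf, blobs$x)$label, blobs$y)
})

test_that("degenerate training inputs are rejected", {
  blobs <- make_blobs()
  expect_error(train_classifier(blobs$x, rep(1L, nrow(blobs$x))),
               "single class")
  expect_error(train_classifier(blobs$x[1:3, ], c(1L, 1L, 0L)),
               "2 examples per class")
  expect_error(predict_classifier(train_classifier(blobs$x, blobs$y,
                                                   fast_svm()),
                                  blobs$x[, 1:3]),
               "mismatch")
})

test_that("cutoff semantics: ties go positive, extremes flip every label", {
  blobs <- make_blobs(n_per_class = 10)
  m <- train_classifier(blobs$x, blobs$y,
                        model_spec("svm", cost = 1, gamma = 0.1, seed = 1))
  sc <- predict_classifier(m, blobs$x)$score
  expect_identical(as.integer(sc >= 0.5), predict_classifier(m, blobs$x)$label)
  expect_true(all(predict_classifier(m, blobs$x, cutoff = 1e-12)$label == 1L))
  # a score exactly at the cutoff is labeled positive
  expect_identical(as.integer(sc >= sc[1]),
                   predict_classifier(m, blobs$x, cutoff = sc[1])$label)
})

test_that("cross_validate reports k folds with mean/sd and guards leakage", {
  ds <- simulate_ppi_dataset(n_pairs = 50, seq_len_nt = 300, effect = 1,
                             seed = 42)
  cv <- cross_validate(ds$pairs, ds$sequences, fast_svm(), k = 5, seed = 42)
  expect_length(cv$folds, 5L)
  expect_setequal(cv$summary$metric,
                  c("acc", "pre", "sen", "spe", "mcc", "f1", "auc"))
  # per-fold standardizer statistics come from that fold's training rows only
  feats <- featurize_pairs(ds$pairs, ds$sequences)
  for (i in seq_along(cv$fold_indices)) {
    f <- cv$fold_indices[[i]]
    expect_equal(cv$fold_standardizers[[i]]$means,
                 unname(colMeans(feats$x[-f, , drop = FALSE])),
                 tolerance = 1e-12)
    expect_equal(cv$fold_standardizers[[i]]$n_fit, nrow(ds$pairs) - length(f))
  }
  # same seed reproduces fold assignment and reports exactly
  cv2 <- cross_validate(ds$pairs, ds$sequences, fast_svm(), k = 5, seed = 42)
  expect_identical(cv$fold_indices, cv2$fold_indices)
  expect_equal(cv$summary, cv2$summary)
})

test_that("a perfectly separable synthetic set cross-validates at 100%", {
  ds <- simulate_ppi_dataset(n_pairs = 50, seq_len_nt = 900, effect = 1,
                             seed = 7)
  cv <- cross_validate(ds$pairs, ds$sequences, fast_svm(seed = 7), k = 5,
                       seed = 7)
  acc <- cv$summary[cv$summary$metric == "acc", ]
  expect_equal(acc$mean, 100)
  expect_equal(acc$sd, 0)
})

test_that("metrics CSV mirrors the reporting layout", {
  ds <- simulate_ppi_dataset(n_pairs = 20, seq_len_nt = 300, effect = 1,
                             seed = 5)
  cv <- cross_validate(ds$pairs, ds$sequences, fast_svm(seed = 5), k = 3,
                       seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(cv, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab),
                   c("fold", "acc", "pre", "sen", "spe", "mcc", "f1", "auc"))
  expect_equal(nrow(tab), 5L)  # 3 folds + mean + sd
  expect_identical(tab$fold[4:5], c("mean", "sd"))
})

test_that("model save/load round-trips predictions and writes a JSON sidecar", {
  ds <- simulate_ppi_dataset(n_pairs = 20, seq_len_nt = 300, effect = 1,
                             seed = 6)
  model <- train_ppi(ds$pairs, ds$sequences, fast_svm(seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  feats <- featurize_pairs(ds$pairs, ds$sequences)
  expect_identical(predict_classifier(back, feats$x)$score,
                   predict_classifier(model, feats$x)$score)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$kind, "svm")
  expect_identical(side$scheme, "Cod5")
})
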