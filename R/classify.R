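#' Classifier specification
#'
#' Describes a model family and its hyperparameter grid. Hyperparameters are
#' chosen by internal cross-validated grid search inside [train_classifier()]
#' (best mean inner-CV accuracy; ties resolved to the first grid point, so
#' the choice is deterministic given the seed).
#'
#' Default grids: for the RBF SVM, cost `c = 2^{-5}, 2^{-3}, ..., 2^{15}`
#' and kernel width `gamma = 2^{-15}, ..., 2^3` (steps of 4x); for the
#' random forest, `n_tree` in \{50, 100, 150, 200\}, `mtry = sqrt(d)`
#' features per split and minimum leaf size 1.
#'
#' @param kind `"svm"` (RBF kernel) or `"rf"`.
#' @param cost,gamma SVM grids (numeric vectors).
#' @param n_tree RF grid of tree counts (all positive, capped at 200 by
#'   default).
#' @param mtry RF features per split; `NULL` = `floor(sqrt(d))`.
#' @param min_leaf RF minimum terminal-node size.
#' @param cutoff Probability threshold for the positive class (in (0,1),
#'   default 0.5; scores `>= cutoff` predict positive).
#' @param inner_k Folds for the internal hyperparameter search (default 3).
#' @param seed Integer seed used for the internal search and any stochastic
#'   fitting.
#' @return Object of class `nvdt_model_spec`.
#' @export
model_spec <- function(kind = c("svm", "rf"),
                       cost = 2^seq(-5, 15, by = 2),
                       gamma = 2^seq(-15, 3, by = 2),
                       n_tree = c(50L, 100L, 150L, 200L),
                       mtry = NULL, min_leaf = 1L,
                       cutoff = 0.5, inner_k = 3L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(cutoff > 0, cutoff < 1, length(cost) >= 1L, length(gamma) >= 1L,
            length(n_tree) >= 1L, all(n_tree > 0))
  structure(list(kind = kind, cost = cost, gamma = gamma, n_tree = n_tree,
                 mtry = mtry, min_leaf = min_leaf, cutoff = cutoff,
                 inner_k = as.integer(inner_k), seed = as.integer(seed)),
            class = "nvdt_model_spec")
}

# Hyperparameter grid as a data.frame in deterministic order.
spec_grid <- function(spec, d) {
  if (spec$kind == "svm") {
    expand.grid(cost = spec$cost, gamma = spec$gamma, KEEP.OUT.ATTRS = FALSE)
  } else {
    mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(d))) else spec$mtry
    expand.grid(n_tree = spec$n_tree, mtry = mtry, min_leaf = spec$min_leaf,
                KEEP.OUT.ATTRS = FALSE)
  }
}

# Fit one classifier with fixed hyperparameters on standardized features.
fit_one <- function(x, y01, spec, params) {
  yf <- factor(y01, levels = c(0L, 1L))
  if (spec$kind == "svm") {
    fit <- e1071::svm(x, yf, kernel = "radial", cost = params$cost,
                      gamma = params$gamma, scale = FALSE)
    # Orient decision values so larger = more positive-class (libsvm sign
    # depends on training-label order).
    dv <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                          "decision.values"))
    ori_cor <- stats::cor(dv, as.numeric(y01))
    orient <- if (is.na(ori_cor) || ori_cor >= 0) 1 else -1
    list(fit = fit, orient = orient)
  } else {
    fit <- with_seed(spec$seed, randomForest::randomForest(
      x, yf, ntree = params$n_tree, mtry = params$mtry,
      nodesize = params$min_leaf))
    list(fit = fit, orient = 1)
  }
}

# Scores in [0, 1] for the positive class from a fitted classifier.
score_one <- function(fitted, spec, x) {
  if (spec$kind == "svm") {
    dv <- as.numeric(attr(predict(fitted$fit, x, decision.values = TRUE),
                          "decision.values"))
    # logistic map of the (oriented) margin distance; 0.5 <=> the decision
    # boundary, so a 0.5 cutoff reproduces the SVM's own labeling
    stats::plogis(fitted$orient * dv)
  } else {
    unname(predict(fitted$fit, x, type = "prob")[, "1"])
  }
}

#' Train an SVM or random-forest pair classifier
#'
#' Fits the Z-score standardizer on the training rows, runs an internal
#' stratified `inner_k`-fold grid search over the spec's hyperparameters
#' (selection by mean held-out accuracy), and refits the winning model on
#' all training rows. Deterministic given `spec$seed`.
#'
#' @param x Raw (unstandardized) pair-feature matrix.
#' @param y Binary labels (0/1), at least 2 examples per class.
#' @param spec An [model_spec()].
#' @return Object of class `nvdt_model`: `spec`, `standardizer`, `fit`,
#'   `chosen` (winning hyperparameters), `search` (grid with mean inner-CV
#'   accuracy), `feature_names`.
#' @export
train_classifier <- function(x, y, spec = model_spec("svm")) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("labels and feature rows differ in length")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; need both 0 and 1")
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  std <- fit_standardizer(x)
  xs <- apply_standardizer(std, x)
  grid <- spec_grid(spec, ncol(xs))
  inner_k <- min(spec$inner_k, min(table(y)))
  folds <- kfold_pairs(data.frame(label = y), k = inner_k, seed = spec$seed,
                       stratified = TRUE)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in folds) {
      fitted <- fit_one(xs[-f, , drop = FALSE], y[-f], spec, grid[g, , drop = FALSE])
      sc <- score_one(fitted, spec, xs[f, , drop = FALSE])
      correct <- correct + sum(as.integer(sc >= spec$cutoff) == y[f])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)  # first max: deterministic tie-break
  fitted <- fit_one(xs, y, spec, grid[best, , drop = FALSE])
  structure(list(spec = spec, standardizer = std, fit = fitted,
                 chosen = as.list(grid[best, , drop = FALSE]),
                 search = cbind(grid, cv_accuracy = acc),
                 feature_names = colnames(x)),
            class = "nvdt_model")
}

#' @export
print.nvdt_model <- function(x, ...) {
  cat("nvdt", toupper(x$spec$kind), "model:",
      length(x$standardizer$means), "features,",
      x$standardizer$n_fit, "training pairs\n")
  cat("chosen hyperparameters:",
      paste(names(x$chosen), unlist(x$chosen), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict interaction labels and scores
#'
#' Applies the model's stored standardizer, scores each row in `[0, 1]`
#' (positive-class probability for RF; logistic-mapped decision value for
#' SVM), and thresholds at `cutoff` (score exactly at the cutoff predicts
#' positive).
#'
#' @param model An `nvdt_model` from [train_classifier()].
#' @param x Raw pair-feature matrix (same feature dimension as training).
#' @param cutoff Threshold; defaults to the spec's (0.5).
#' @return List with `score` (numeric) and `label` (integer 0/1).
#' @export
predict_classifier <- function(model, x, cutoff = NULL) {
  stopifnot(inherits(model, "nvdt_model"))
  if (is.null(cutoff)) cutoff <- model$spec$cutoff
  xs <- apply_standardizer(model$standardizer, as.matrix(x))
  score <- score_one(model$fit, model$spec, xs)
  list(score = score, label = as.integer(score >= cutoff))
}

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length 0/1 vectors (an error otherwise; empty
#'   input is an error).
#' @return List of class `nvdt_confusion` with `tp`, `fp`, `tn`, `fn`
#'   (their sum is the number of evaluated pairs).
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 tn = sum(y_true == 0L & y_pred == 0L),
                 fn = sum(y_true == 1L & y_pred == 0L)),
            class = "nvdt_confusion")
}

# ROC curve by descending score threshold with tie grouping.
roc_points <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  # cumulative counts at each distinct threshold (ties collapse together)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y == 1L)[last_of_tie]
  cum_fp <- cumsum(y == 0L)[last_of_tie]
  P <- sum(y_true == 1L)
  Nn <- sum(y_true == 0L)
  data.frame(fpr = c(0, cum_fp / max(Nn, 1L)),
             tpr = c(0, cum_tp / max(P, 1L)))
}

#' Area under the ROC curve
#'
#' Trapezoidal-rule AUC of the ROC obtained by sweeping the score threshold
#' (tied scores are grouped, so the value equals the Mann-Whitney pairwise
#' ordering statistic with ties counted 0.5).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param y_true 0/1 labels.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
auc_score <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2L) return(NA_real_)
  r <- roc_points(scores, y_true)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Classification metric suite
#'
#' Accuracy, precision, sensitivity, specificity, Matthews correlation
#' coefficient and F1 from confusion counts, plus trapezoidal AUC when
#' scores are supplied. A metric whose denominator is zero is reported as 0
#' and listed in the `undefined` field.
#'
#' @param cm An `nvdt_confusion` (or anything [confusion_counts()] accepts
#'   via `y_true`/`y_pred`).
#' @param scores Optional numeric scores for AUC.
#' @param y_true Labels matching `scores` (required when `scores` given;
#'   total count must match the confusion counts).
#' @return Object of class `nvdt_metrics`: named list `acc`, `pre`, `sen`,
#'   `spe`, `mcc`, `f1` (fractions), `auc` (or `NA`), `undefined`
#'   (character vector of zero-denominator metrics), `cm`.
#' @export
classification_metrics <- function(cm, scores = NULL, y_true = NULL) {
  stopifnot(inherits(cm, "nvdt_confusion"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn, "acc")
  pre <- safe_div(tp, tp + fp, "pre")
  sen <- safe_div(tp, tp + fn, "sen")
  spe <- safe_div(tn, tn + fp, "spe")
  mcc_den <- sqrt(prod(as.numeric(c(tp + fn, tn + fp, tp + fp, tn + fn))))
  mcc <- safe_div(as.numeric(tp) * tn - as.numeric(fp) * fn, mcc_den, "mcc")
  f1 <- if (pre + sen == 0) {
    undefined <- c(undefined, "f1")
    0
  } else 2 * pre * sen / (pre + sen)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true is required to compute AUC from scores")
    if (length(scores) != tp + tn + fp + fn)
      stop("score count does not match the confusion totals")
    auc <- auc_score(scores, y_true)
  }
  structure(list(acc = acc, pre = pre, sen = sen, spe = spe, mcc = mcc,
                 f1 = f1, auc = auc, undefined = undefined, cm = cm),
            class = "nvdt_metrics")
}

#' @export
print.nvdt_metrics <- function(x, ...) {
  cat(sprintf("Acc %.2f%%  Pre %.2f%%  Sen %.2f%%  Spe %.2f%%  MCC %.2f%%  F1 %.2f%%  AUC %s\n",
              100 * x$acc, 100 * x$pre, 100 * x$sen, 100 * x$spe,
              100 * x$mcc, 100 * x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  if (length(x$undefined) > 0)
    cat("zero-denominator metrics reported as 0:",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# Metrics list -> one-row data.frame (percentages except AUC).
metrics_row <- function(m) {
  data.frame(acc = 100 * m$acc, pre = 100 * m$pre, sen = 100 * m$sen,
             spe = 100 * m$spe, mcc = 100 * m$mcc, f1 = 100 * m$f1,
             auc = m$auc)
}

#' Train a PPI/PPNI model from sequences and labeled pairs
#'
#' End-to-end wrapper: featurizes the pairs ([featurize_pairs()]), then
#' trains ([train_classifier()]). The variant and scheme are stored on the
#' model so that prediction-time featurization matches.
#'
#' @param pairs Labeled pair data.frame (`id_a`, `id_b`, `label`).
#' @param sequences Named character vector of CDS sequences.
#' @param spec A [model_spec()].
#' @param variant,scheme,kmer_normalize Featurization options, see
#'   [featurize_pairs()].
#' @param augment_orders Include both orders of each pair in training.
#' @return An `nvdt_model` with `variant` and `scheme` fields set.
#' @export
train_ppi <- function(pairs, sequences, spec = model_spec("svm"),
                      variant = "NVDT", scheme = "Cod5",
                      augment_orders = FALSE, kmer_normalize = FALSE) {
  feats <- featurize_pairs(pairs, sequences, variant = variant,
                           scheme = scheme, augment_orders = augment_orders,
                           kmer_normalize = kmer_normalize)
  if (anyNA(feats$label)) stop("all training pairs must be labeled")
  model <- train_classifier(feats$x, feats$label, spec)
  model$variant <- variant
  model$scheme <- scheme
  model$kmer_normalize <- kmer_normalize
  model
}

#' Evaluate a trained model on labeled pairs
#'
#' @param model An `nvdt_model` from [train_ppi()].
#' @param pairs Labeled pair data.frame.
#' @param sequences Named character vector of CDS sequences.
#' @return An `nvdt_metrics` report, with `scores` and `labels` attached as
#'   attributes.
#' @export
evaluate_ppi <- function(model, pairs, sequences) {
  feats <- featurize_pairs(pairs, sequences, variant = model$variant,
                           scheme = model$scheme,
                           kmer_normalize = isTRUE(model$kmer_normalize))
  pred <- predict_classifier(model, feats$x)
  m <- classification_metrics(confusion_counts(feats$label, pred$label),
                              scores = pred$score, y_true = feats$label)
  attr(m, "scores") <- pred$score
  attr(m, "labels") <- pred$label
  m
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold the standardizer and classifier are fitted on the other
#' k - 1 folds only (no statistics leak from the held-out fold) and the
#' fold is scored with the full metric suite. Results are reported per fold
#' and as mean +/- sample (n-1) standard deviation, the conventional k-fold
#' summary.
#'
#' @param pairs Labeled pair data.frame.
#' @param sequences Named character vector of CDS sequences.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param variant,scheme,kmer_normalize Featurization options.
#' @return Object of class `nvdt_cv`: `folds` (list of `nvdt_metrics`),
#'   `summary` (data.frame of mean and sd per metric, percentages except
#'   AUC), `fold_indices`, `fold_standardizers` (the per-fold training
#'   statistics, for leakage auditing), `k`, `seed`.
#' @export
cross_validate <- function(pairs, sequences, spec = model_spec("svm"),
                           k = 5L, seed = 1L, variant = "NVDT",
                           scheme = "Cod5", kmer_normalize = FALSE) {
  if (anyNA(pairs$label)) stop("all pairs must be labeled for cross-validation")
  feats <- featurize_pairs(pairs, sequences, variant = variant,
                           scheme = scheme, kmer_normalize = kmer_normalize)
  folds <- kfold_pairs(pairs, k = k, seed = seed, stratified = TRUE)
  fold_std <- vector("list", length(folds))
  reports <- lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    model <- train_classifier(feats$x[-f, , drop = FALSE], feats$label[-f], spec)
    fold_std[[i]] <<- model$standardizer
    pred <- predict_classifier(model, feats$x[f, , drop = FALSE])
    classification_metrics(confusion_counts(feats$label[f], pred$label),
                           scores = pred$score, y_true = feats$label[f])
  })
  tab <- do.call(rbind, lapply(reports, metrics_row))
  summary <- data.frame(metric = names(tab),
                        mean = vapply(tab, mean, numeric(1)),
                        sd = vapply(tab, stats::sd, numeric(1)),
                        row.names = NULL)
  structure(list(folds = reports, summary = summary, fold_indices = folds,
                 fold_standardizers = fold_std, k = k, seed = seed),
            class = "nvdt_cv")
}

#' @export
print.nvdt_cv <- function(x, ...) {
  cat(x$k, "fold cross-validation (mean +/- sd):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (s$metric[i] == "auc")
      cat(sprintf("  AUC   %.4f +/- %.4f\n", s$mean[i], s$sd[i]))
    else
      cat(sprintf("  %-4s %6.2f +/- %.2f %%\n", toupper(s$metric[i]),
                  s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Write a cross-validation (or single) metrics table as CSV
#'
#' Columns mirror the standard reporting layout: Acc., Pre., Sen., Spe.,
#' MCC, F-score as percentages and AUC as a fraction.
#'
#' @param x An `nvdt_cv` or `nvdt_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  if (inherits(x, "nvdt_cv")) {
    per_fold <- do.call(rbind, lapply(x$folds, metrics_row))
    per_fold <- cbind(fold = seq_len(nrow(per_fold)), per_fold)
    mean_row <- cbind(fold = "mean", as.data.frame(as.list(colMeans(per_fold[-1]))))
    sd_row <- cbind(fold = "sd",
                    as.data.frame(lapply(per_fold[-1], stats::sd)))
    out <- rbind(per_fold, mean_row, sd_row)
  } else if (inherits(x, "nvdt_metrics")) {
    out <- metrics_row(x)
  } else stop("unsupported object for write_metrics_csv")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model
#'
#' The model is serialized with `saveRDS()`; a human-readable JSON sidecar
#' (`<path>.json`) records the spec, the chosen hyperparameters and the
#' standardizer statistics.
#'
#' @param model An `nvdt_model`.
#' @param path Output path for the RDS archive.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nvdt_model"))
  saveRDS(model, path)
  side <- list(kind = model$spec$kind, chosen = model$chosen,
               cutoff = model$spec$cutoff, variant = model$variant,
               scheme = model$scheme,
               standardizer = list(means = model$standardizer$means,
                                   stds = model$standardizer$stds,
                                   n_fit = model$standardizer$n_fit),
               package_version = as.character(utils::packageVersion("nvdt")))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nvdt_model")) stop("not an nvdt model archive: ", path)
  model
}
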