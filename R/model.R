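#' Rank-based ROC AUC
#'
#' Area under the ROC curve via the Mann-Whitney rank statistic: the
#' probability that a random positive scores above a random negative (ties
#' count half).
#'
#' @param scores numeric predictor or predicted probability.
#' @param labels 0/1 vector; 1 is the positive (error) class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  c(accuracy = (tp + tn) / length(truth),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Train and evaluate a logistic-regression error classifier
#'
#' Stratified train/test split (`caret::createDataPartition`), logistic
#' regression trained with repeated 10-fold cross-validation (10 repeats,
#' `caret::train`, method `"glm"`), and evaluation on the held-out test
#' set: rank-based ROC AUC plus accuracy, precision, sensitivity and
#' specificity from the confusion matrix at probability threshold 0.5
#' (positive class = error, label 1). The model p-value is a
#' likelihood-ratio test of the training-set fit against the
#' intercept-only model. Fully deterministic given `seed`.
#'
#' @param table data frame of feature columns (already selected).
#' @param labels 0/1 vector; error-free = 0, error = 1.
#' @param split_fraction training fraction, in `[0.6, 0.8]` (default 0.7).
#' @param seed integer seed controlling split and CV folds.
#' @param cv_folds,cv_repeats cross-validation geometry (defaults 10, 10).
#' @return list of class `model_report`: `coefficients` (with p-values),
#'   `metrics` (auc, accuracy, precision, sensitivity, specificity),
#'   `model_p` (likelihood-ratio p), `cv` (resample summary),
#'   `final_model` (the acceptance-gate flag), `n_train`, `n_test`,
#'   `features`, `separation` flag.
#' @export
train_and_evaluate <- function(table, labels, split_fraction = 0.7, seed = 1,
                               cv_folds = 10, cv_repeats = 10) {
  stopifnot(split_fraction >= 0.6, split_fraction <= 0.8)
  table <- as.data.frame(table)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  if (min(base::table(y)) < 2L) stop("both classes must be present")
  yf <- factor(ifelse(y == 1L, "error", "error_free"),
               levels = c("error_free", "error"))
  set.seed(seed)
  idx <- caret::createDataPartition(yf, p = split_fraction, list = FALSE)[, 1]
  tr_x <- table[idx, , drop = FALSE]; tr_y <- yf[idx]
  te_x <- table[-idx, , drop = FALSE]; te_y <- yf[-idx]
  if (min(base::table(tr_y)) < cv_folds / 2) {
    stop("stratification error: a CV fold would miss a class")
  }
  ctrl <- caret::trainControl(method = "repeatedcv", number = cv_folds,
                              repeats = cv_repeats, classProbs = TRUE,
                              summaryFunction = caret::twoClassSummary)
  fit <- suppressWarnings(
    caret::train(x = tr_x, y = tr_y, method = "glm",
                 family = binomial(), trControl = ctrl, metric = "ROC"))
  prob <- suppressWarnings(
    predict(fit, newdata = te_x, type = "prob")[, "error"])
  pred <- as.integer(prob >= 0.5)
  truth <- as.integer(te_y == "error")
  metrics <- c(auc = rank_auc(prob, truth), confusion_metrics(pred, truth))

  glm_fit <- fit_logistic(tr_x, as.integer(tr_y == "error"))
  null_fit <- glm(y ~ 1, data = data.frame(y = as.integer(tr_y == "error")),
                  family = binomial())
  lr <- as.numeric(null_fit$deviance - glm_fit$deviance)
  df <- length(coef(glm_fit)) - 1L
  model_p <- if (df > 0) pchisq(lr, df, lower.tail = FALSE) else 1
  coefs <- summary(glm_fit)$coefficients

  report <- structure(list(
    coefficients = coefs, metrics = metrics, model_p = model_p,
    cv = fit$resample, cv_summary = colMeans(fit$resample[, 1:3]),
    n_train = nrow(tr_x), n_test = nrow(te_x),
    features = names(table),
    separation = isTRUE(attr(glm_fit, "separation")),
    final_model = NA), class = "model_report")
  report$final_model <- gate_final_model(report)
  report
}

#' Final-model acceptance gate
#'
#' A candidate becomes a final model iff AUC, accuracy, precision,
#' sensitivity and specificity are all at least 0.8 (inclusive) and the
#' model is significant at `p < 0.05`.
#'
#' @param report a `model_report` (or a list with `metrics` and `model_p`).
#' @return logical flag.
#' @export
gate_final_model <- function(report) {
  m <- report$metrics[c("auc", "accuracy", "precision", "sensitivity",
                        "specificity")]
  isTRUE(all(!is.na(m)) && all(m >= 0.8) && report$model_p < 0.05)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %d features, train/test %d/%d\n  %s\n  model p = %.3g, final model: %s\n",
    length(x$features), x$n_train, x$n_test,
    paste(sprintf("%s=%.3f", names(x$metrics), x$metrics), collapse = " "),
    x$model_p, x$final_model))
  invisible(x)
}
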