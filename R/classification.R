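#' Train a soft-margin linear support vector machine
#'
#' Thin wrapper over the libsvm solver in \pkg{e1071} (an SMO-family
#' decomposition method) with the linear kernel `K(x, y) = <x, y>`, exposing
#' the primal weight vector and bias. The decision value `<w, x> + b` is
#' oriented so that positive values predict the case group.
#'
#' @param X subjects x features numeric matrix.
#' @param y binary labels (factor or character); `case`/`control` in the
#'   pipeline, but any two labels work (the first factor level is positive).
#' @param C margin-violation cost.
#' @return Object of class `cc_svm`: `w`, `b`, `C`, `levels`, `positive`
#'   and the underlying fit.
#' @export
train_linear_svm <- function(X, y, C = 1.0) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L || any(table(y) == 0L))
    cc_stop("one-class", "both classes must be present to train")
  if (anyNA(X)) cc_stop("missing-values", "X must not contain missing values")
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  pos <- levels(y)[1L]
  d <- drop(X %*% w) + b
  pred <- predict(fit, X)
  # align sign convention: decision > 0 <=> predicted positive class
  agree <- mean((d > 0) == (pred == pos))
  if (!is.nan(agree) && agree < 0.5) { w <- -w; b <- -b }
  structure(list(w = w, b = b, C = C, levels = levels(y), positive = pos,
                 fit = fit), class = "cc_svm")
}

#' @export
predict.cc_svm <- function(object, newdata, ...) {
  d <- drop(as.matrix(newdata) %*% object$w) + object$b
  lab <- ifelse(d > 0, object$positive,
                setdiff(object$levels, object$positive))
  list(class = factor(lab, levels = object$levels), decision = d)
}

#' Stratified cross-validation folds
#'
#' Shuffles each class independently (reproducibly from `seed`) and deals
#' its members round-robin across folds, so fold sizes differ by at most one
#' within each class. If a class has fewer members than `folds`, the number
#' of folds is reduced to the smallest class size with a warning.
#'
#' @param y class labels.
#' @param folds requested number of folds.
#' @param seed integer seed for the shuffling.
#' @return Integer fold assignment per subject (attribute `folds` gives the
#'   realized fold count).
#' @export
make_folds <- function(y, folds = 10L, seed = 1L) {
  y <- factor(y)
  k <- as.integer(folds)
  mn <- min(table(y))
  if (mn < k) {
    cc_warn("folds-reduced",
            sprintf("reducing folds from %d to smallest class size %d", k, mn))
    k <- mn
  }
  assign <- integer(length(y))
  extra_load <- integer(k)        # folds already carrying a remainder member
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_lv <- length(idx)
      base <- n_lv %/% k
      n_extra <- n_lv %% k
      counts <- rep(base, k)
      if (n_extra > 0L) {
        # spread remainder members over the folds least loaded so far, so
        # overall fold sizes differ by at most one
        pick <- order(extra_load + stats::runif(k))[seq_len(n_extra)]
        counts[pick] <- counts[pick] + 1L
        extra_load[pick] <- extra_load[pick] + 1L
      }
      assign[sample(idx)] <- rep(seq_len(k), counts)
    }
  })
  structure(assign, folds = k)
}

#' Cross-validated out-of-fold SVM predictions
#'
#' Stratified k-fold cross-validation of the linear SVM: each subject is
#' predicted exactly once by a model that never saw it. Features are
#' standardized with the training fold's means and standard deviations
#' (applied unchanged to the held-out fold); disable with
#' `standardize = FALSE`.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @param folds number of folds.
#' @param seed seed for the fold assignment.
#' @param C SVM cost.
#' @param standardize standardize features per training fold.
#' @return Data frame: `index`, `fold`, `truth`, `pred`, `decision`.
#' @export
cross_validate <- function(X, y, folds = 10L, seed = 1L, C = 1.0,
                           standardize = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) cc_stop("one-class", "both classes must be present")
  fold <- make_folds(y, folds, seed)
  k <- attr(fold, "folds")
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  dec <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2L, stats::sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sg, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sg, "/")
    }
    m <- train_linear_svm(Xtr, y[tr], C = C)
    pr <- predict(m, Xte)
    pred[te] <- pr$class
    dec[te] <- pr$decision
  }
  out <- data.frame(index = seq_along(y), fold = as.integer(fold), truth = y,
                    pred = pred, decision = dec)
  attr(out, "folds") <- k
  out
}

#' Classification performance metrics
#'
#' Confusion matrix and the standard machine-learning metric suite, computed
#' one-vs-rest per class: precision `tp/(tp+fp)`, recall `tp/(tp+fn)`,
#' F-measure `2*precision*recall/(precision+recall)`, plus overall accuracy
#' and error rate. Sensitivity is the recall of the case class and
#' specificity the recall of the control class. An undefined precision
#' (no positive predictions) is reported as `NA` with a warning.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return List with `confusion` (table), `per_class` (data frame),
#'   `accuracy`, `error_rate`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- factor(y_true)
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  stopifnot(length(y_true) == length(y_pred))
  conf <- table(truth = y_true, predicted = y_pred)
  per <- lapply(levels(y_true), function(lv) {
    tp <- sum(y_true == lv & y_pred == lv)
    fp <- sum(y_true != lv & y_pred == lv)
    fn <- sum(y_true == lv & y_pred != lv)
    tn <- sum(y_true != lv & y_pred != lv)
    if (tp + fp == 0L) {
      cc_warn("precision-undefined",
              sprintf("no predictions for class '%s'; precision undefined", lv))
      prec <- NA_real_
    } else prec <- tp / (tp + fp)
    rec <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
    f <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
         else 2 * prec * rec / (prec + rec)
    data.frame(class = lv, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec, f_measure = f)
  })
  per <- do.call(rbind, per)
  acc <- mean(y_true == y_pred)
  sens <- per$recall[per$class == "case"]
  spec <- per$recall[per$class == "control"]
  list(confusion = conf, per_class = per, accuracy = acc,
       error_rate = 1 - acc,
       sensitivity = if (length(sens)) sens else NA_real_,
       specificity = if (length(spec)) spec else NA_real_)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values, recording the
#' true-positive rate against the false-positive rate; tied scores move as
#' one simultaneous step (a diagonal ROC segment). The AUC is the trapezoid
#' area under the resulting polyline.
#'
#' @param y_true labels.
#' @param scores decision values; larger favours the positive class.
#' @param positive the positive class label.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores, positive) {
  stopifnot(all(is.finite(scores)))
  pos <- y_true == positive
  if (all(pos) || !any(pos))
    cc_stop("auc-undefined", "ROC needs both classes in y_true")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Cross-validated stratification report for a cohort
#'
#' Runs stratified k-fold cross-validation of the linear SVM on the 99
#' centile widths and assembles the full report: confusion matrix,
#' per-class precision/recall/F, accuracy and error rate, sensitivity and
#' specificity, and one ROC curve per class as positive (the control-class
#' curve uses the negated decision values), all from the pooled out-of-fold
#' predictions.
#'
#' @param cohort a [cc_cohort()].
#' @param C SVM cost.
#' @param folds number of CV folds.
#' @param seed fold-assignment seed (recorded in the report).
#' @param standardize per-fold feature standardization.
#' @return Object of class `cc_classification_report`.
#' @export
classify_cohort <- function(cohort, C = 1.0, folds = 10L, seed = 1L,
                            standardize = TRUE) {
  stopifnot(inherits(cohort, "cc_cohort"))
  cv <- cross_validate(cohort$widths, cohort$group, folds = folds,
                       seed = seed, C = C, standardize = standardize)
  met <- classification_metrics(cv$truth, cv$pred)
  roc_case <- roc_auc(cv$truth, cv$decision, positive = "case")
  roc_ctrl <- roc_auc(cv$truth, -cv$decision, positive = "control")
  met$per_class$auc <- c(roc_case$auc, roc_ctrl$auc)[
    match(met$per_class$class, c("case", "control"))]
  structure(list(cv = cv, confusion = met$confusion,
                 per_class = met$per_class,
                 accuracy = met$accuracy, error_rate = met$error_rate,
                 sensitivity = met$sensitivity, specificity = met$specificity,
                 roc = list(case = roc_case, control = roc_ctrl),
                 folds = attr(cv, "folds") %||% folds, seed = seed,
                 C = C, standardize = standardize),
            class = "cc_classification_report")
}

#' @export
print.cc_classification_report <- function(x, ...) {
  cat(sprintf("<cc_classification_report> accuracy %.3f, AUC(case) %.3f, AUC(control) %.3f\n",
              x$accuracy, x$roc$case$auc, x$roc$control$auc))
  print(x$confusion)
  invisible(x)
}
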