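#' Confusion matrix from true and predicted labels
#'
#' Rows are true classes, columns predicted classes. Abstentions (`NA`
#' calls) are excluded from the count table but tallied per true class in
#' the `"abstain"` attribute — they are never silently dropped.
#'
#' @param truth Character vector of true labels.
#' @param calls Character vector of predicted labels (`NA` = abstain).
#' @param labels Class ordering; defaults to the sorted union of the true
#'   labels. Non-`NA` calls outside this set are an error.
#' @return Object of class `confusion_matrix`: an integer k x k matrix with
#'   a per-class abstention count in `attr(, "abstain")`.
#' @export
confusion_from_calls <- function(truth, calls, labels = NULL) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(calls))
    stop("'truth' and 'calls' must have equal length")
  truth <- as.character(truth); calls <- as.character(calls)
  if (is.null(labels)) labels <- sort(unique(truth))
  if (!all(truth %in% labels))
    stop("unknown label in 'truth'")
  bad <- !is.na(calls) & !calls %in% labels
  if (any(bad))
    stop("unknown label in 'calls': ", paste(unique(calls[bad]), collapse = ", "))
  keep <- !is.na(calls)
  counts <- table(factor(truth[keep], levels = labels),
                  factor(calls[keep], levels = labels))
  m <- matrix(as.integer(counts), nrow = length(labels),
              dimnames = list(truth = labels, predicted = labels))
  abst <- table(factor(truth[!keep], levels = labels))
  structure(m, abstain = as.integer(abst), class = "confusion_matrix")
}

#' Coerce a plain count matrix to a `confusion_matrix`
#'
#' @param m Square numeric matrix of nonnegative counts with matching
#'   dimnames (rows = true class, columns = predicted class).
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (is.null(rownames(m))) stop("row names (class labels) required")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(truth = rownames(m), predicted = rownames(m))
  structure(m, abstain = integer(nrow(m)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x; attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y)
  ab <- attr(x, "abstain")
  if (!is.null(ab) && sum(ab) > 0)
    cat(sprintf("abstentions: %d\n", sum(ab)))
  invisible(x)
}

#' One-vs-rest binary counts for one class
#'
#' Collapses a k-class confusion matrix to (TP, FP, TN, FN) for the named
#' positive class: TP is the diagonal entry, FN the rest of the row, FP the
#' rest of the column, TN everything else.
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @param positive Positive class name.
#' @return Object of class `binary_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
one_vs_rest <- function(cm, positive) {
  m <- unclass(cm)
  labels <- rownames(m)
  if (!positive %in% labels) stop("unknown class '", positive, "'")
  i <- match(positive, labels)
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "binary_counts")
}

#' Accuracy, precision, recall and F1 from binary counts
#'
#' accuracy = (TP+TN)/(TP+FP+TN+FN); precision = TP/(TP+FP);
#' recall = TP/(TP+FN); F1 = 2TP/(2TP+FP+FN). A ratio with zero denominator
#' is undefined and reported as `NA`, never as 0.
#'
#' @param bc A `binary_counts` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
binary_metrics <- function(bc) {
  tp <- bc$tp; fp <- bc$fp; tn <- bc$tn; fn <- bc$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all-zero counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (tp + tn) / total,
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    f1 = ratio(2 * tp, 2 * tp + fp + fn))
}

# Display-only half-up rounding of a fraction to a 2-decimal percentage.
# All numeric comparisons in tests run on the unrounded fractions.
fmt_percent <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_,
         formatC(floor(x * 100 * 10^digits + 0.5) / 10^digits,
                 format = "f", digits = digits))
}

#' Per-class one-vs-rest metrics report for a confusion matrix
#'
#' Applies [one_vs_rest()] + [binary_metrics()] to every class. Fractions
#' are carried exactly; the `*_pct` columns are 2-decimal percent strings
#' for display.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `metrics_report`: data.frame with one row per
#'   class (`class`, `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `recall`, `f1`, plus formatted `*_pct` columns).
#' @export
metrics_report <- function(cm) {
  labels <- rownames(unclass(cm))
  rows <- lapply(labels, function(cl) {
    bc <- one_vs_rest(cm, cl)
    met <- binary_metrics(bc)
    data.frame(class = cl, tp = bc$tp, fp = bc$fp, tn = bc$tn, fn = bc$fn,
               accuracy = met["accuracy"], precision = met["precision"],
               recall = met["recall"], f1 = met["f1"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (m in c("accuracy", "precision", "recall", "f1"))
    out[[paste0(m, "_pct")]] <- fmt_percent(out[[m]])
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  print.data.frame(x[, c("class", "tp", "fp", "tn", "fn",
                         "accuracy_pct", "precision_pct", "recall_pct",
                         "f1_pct")], row.names = FALSE)
  invisible(x)
}

#' Subject-rotating nested split plan
#'
#' Builds the nested cross-validation / cross-testing plan used for
#' subject-level holdout: each subject is the test subject in exactly one
#' group of folds, and within that group every remaining subject takes the
#' validation role once, the others training. With 5 subjects this yields
#' 5 x 4 = 20 (train, validation, test) triples; the three roles are
#' disjoint in every triple.
#'
#' @param subject_ids Character or integer vector of distinct subject ids
#'   (>= 3).
#' @param seed Optional seed; when given, the rotation order is a seeded
#'   permutation of the subjects (the plan's coverage is unaffected).
#' @return Object of class `split_plan`: data.frame with columns `fold`,
#'   `test`, `validation` and list-column `train`.
#' @export
make_split_plan <- function(subject_ids, seed = NULL) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) < 3L) stop("need at least 3 subjects for a nested split")
  if (!is.null(seed)) {
    set.seed(seed)
    ids <- sample(ids)
  }
  rows <- list()
  for (test in ids) {
    rest <- setdiff(ids, test)
    for (val in rest) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = test, validation = val, stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  plan$fold <- seq_len(nrow(plan))
  plan$train <- lapply(seq_len(nrow(plan)),
                       function(i) setdiff(ids, c(plan$test[i], plan$validation[i])))
  plan <- plan[, c("fold", "test", "validation", "train")]
  class(plan) <- c("split_plan", "data.frame")
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d folds, %d test subjects\n",
              nrow(x), length(unique(x$test))))
  df <- data.frame(fold = x$fold, test = x$test, validation = x$validation,
                   train = vapply(x$train, paste, character(1), collapse = "+"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Subject-level cross-testing of the attenuation classifier
#'
#' For each held-out test subject, fits the Gaussian classifier (and, if
#' `positive` is named, the crossing-point threshold) on the training
#' subjects only, classifies the held-out subject's images, and accumulates
#' a pooled confusion matrix. The validation rotations of the plan carry no
#' role for this method — the threshold rule has no hyperparameters — so
#' each test subject is evaluated once, on the model fitted to all
#' remaining subjects. Images with non-computable attenuation abstain and
#' are tallied separately.
#'
#' @param mu_table data.frame from [dataset_mu()] (columns `subject_id`,
#'   `label`, `mu`, `valid`).
#' @param plan A [make_split_plan()] result covering the table's subjects.
#' @param positive Optional positive class; when named, evaluation is
#'   two-class (positive vs `"rest"`) using the crossing-point threshold,
#'   otherwise multi-class by Gaussian likelihood.
#' @return Object of class `cross_test_result`: list with `pooled`
#'   (confusion matrix over all held-out predictions), `per_fold` (named
#'   list of [metrics_report()]s, one per test subject), `abstentions`
#'   (per-class counts) and `plan`.
#' @export
cross_test_attenuation <- function(mu_table, plan, positive = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  subjects <- unique(plan$test)
  missing_subj <- setdiff(subjects, unique(mu_table$subject_id))
  if (length(missing_subj))
    stop("subjects in plan but not in table: ", paste(missing_subj, collapse = ", "))

  all_classes <- sort(unique(mu_table$label))
  truth_all <- character(0); calls_all <- character(0)
  per_fold <- list()
  abst <- stats::setNames(integer(length(all_classes)), all_classes)

  for (test_subj in subjects) {
    train <- mu_table[mu_table$subject_id != test_subj, ]
    test <- mu_table[mu_table$subject_id == test_subj, ]
    trainable <- train[train$valid & is.finite(train$mu), ]
    # classes that are computable somewhere must be present in this fold's
    # training data; classes that never yield a mu (pelvis) are exempt
    computable_classes <- sort(unique(
      mu_table$label[mu_table$valid & is.finite(mu_table$mu)]))
    absent <- setdiff(computable_classes, unique(trainable$label))
    if (length(absent))
      stop(sprintf("fold with test subject %s: class(es) %s missing from training data",
                   test_subj, paste(absent, collapse = ", ")))
    fit <- atten_classifier(mu ~ label, trainable, positive = positive)
    calls <- predict(fit, test$mu)
    truth <- test$label
    if (!is.null(positive))
      truth <- ifelse(truth == positive, positive, "rest")

    na_idx <- is.na(calls)
    for (cl in unique(test$label[na_idx]))
      abst[cl] <- abst[cl] + sum(test$label[na_idx] == cl)

    labels_fold <- if (!is.null(positive)) c(positive, "rest")
                   else sort(unique(trainable$label))
    keep <- truth %in% labels_fold
    cm_fold <- confusion_from_calls(truth[keep], calls[keep], labels_fold)
    per_fold[[test_subj]] <- metrics_report(cm_fold)
    truth_all <- c(truth_all, truth[keep])
    calls_all <- c(calls_all, calls[keep])
  }

  labels_pool <- if (!is.null(positive)) c(positive, "rest")
                 else sort(unique(truth_all))
  pooled <- confusion_from_calls(truth_all, calls_all, labels_pool)
  structure(list(pooled = pooled, per_fold = per_fold,
                 abstentions = abst, plan = plan),
            class = "cross_test_result")
}

#' @export
print.cross_test_result <- function(x, ...) {
  cat("Subject-level cross-testing (pooled held-out confusion matrix)\n")
  print(x$pooled)
  if (sum(x$abstentions) > 0) {
    cat("abstentions by true class:\n")
    print(x$abstentions[x$abstentions > 0])
  }
  cat("\nPooled one-vs-rest metrics:\n")
  print(metrics_report(x$pooled))
  invisible(x)
}
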