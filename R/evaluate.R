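#' One-vs-rest AUC by the rank statistic
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U of
#' the positive-class scores against the rest, with midrank (half) credit
#' for ties — identical to brute-force counting of concordant pairs.
#'
#' @param scores Numeric scores for the positive class.
#' @param positive Logical vector (TRUE = positive) of the same length.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Per-class one-vs-rest confusion counts and the derived rates: accuracy
#' `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, and the F1 score
#' `2 * precision * recall / (precision + recall)` (the harmonic mean of
#' precision and recall; 0 when TP = 0). With per-class score columns,
#' one-vs-rest AUCs ([auc_rank()]) and their unweighted macro average are
#' added. Percentages are reported rounded half-up to 2 decimals, F1 to 3,
#' AUC to 2; unrounded values are kept alongside.
#'
#' @param true_labels Character/factor vector of reference classes.
#' @param predicted_labels Same length, predicted classes.
#' @param scores Optional numeric matrix or data frame, one column per
#'   class (named), of predicted class scores for AUC.
#' @return A `metrics_report`: list with `per_class` tibble (one row per
#'   class), `accuracy_overall`, `macro_auc`, `n`. Classes absent from the
#'   reference get `NA` sensitivity (undefined, not 0).
#' @export
evaluate_classification <- function(true_labels, predicted_labels, scores = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  classes <- sort(unique(c(true_labels, predicted_labels,
                           if (!is.null(scores)) colnames(scores))))
  N <- length(true_labels)
  rows <- lapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    tn <- N - tp - fp - fn
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    f1 <- f1_score(prec, sens)
    auc <- if (!is.null(scores) && cl %in% colnames(scores)) {
      auc_rank(as.numeric(scores[, cl]), true_labels == cl)
    } else NA_real_
    tibble::tibble(
      class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = (tp + tn) / N, sensitivity = sens, specificity = spec,
      precision = prec, f1 = f1, auc = auc,
      accuracy_pct = round_half_up(100 * (tp + tn) / N, 2),
      sensitivity_pct = round_half_up(100 * sens, 2),
      specificity_pct = round_half_up(100 * spec, 2),
      precision_pct = round_half_up(100 * prec, 2),
      f1_3dp = round_half_up(f1, 3),
      auc_2dp = round_half_up(auc, 2)
    )
  })
  per_class <- dplyr::bind_rows(rows)
  aucs <- per_class$auc[!is.na(per_class$auc)]
  structure(
    list(
      per_class = per_class,
      accuracy_overall = mean(true_labels == predicted_labels),
      macro_auc = if (length(aucs)) mean(aucs) else NA_real_,
      n = N
    ),
    class = "metrics_report"
  )
}

#' F1 score from precision and recall
#'
#' `2 * precision * recall / (precision + recall)`; 0 when both are 0.
#' Accepts either fractions or percentages (both arguments on the same
#' scale).
#'
#' @param precision,recall Numeric (scalar or vector).
#' @return F1 on the fraction scale (percent inputs are rescaled by 100).
#' @export
f1_score <- function(precision, recall) {
  pr <- cbind(precision, recall)
  if (any(pr > 1, na.rm = TRUE)) pr <- pr / 100
  p <- pr[, 1]; r <- pr[, 2]
  out <- ifelse(is.na(p) | is.na(r), NA_real_,
                ifelse(p + r == 0, 0, 2 * p * r / (p + r)))
  unname(out)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, overall accuracy %.2f%%",
              x$n, 100 * x$accuracy_overall))
  if (!is.na(x$macro_auc)) cat(sprintf(", macro-AUC %.2f", round_half_up(x$macro_auc, 2)))
  cat("\n")
  print(x$per_class[, c("class", "accuracy_pct", "sensitivity_pct",
                        "specificity_pct", "precision_pct", "f1_3dp", "auc_2dp")])
  invisible(x)
}

#' Nearest-centroid baseline classifier
#'
#' A transparent score provider standing where a trained network would:
#' class centroids are fit on standardized training features and test
#' scores are an inverse-distance softmax over classes. Any score provider
#' with the same interface can be plugged into the evaluation layer.
#'
#' @param train Tibble of training rows with a `class_label` column and
#'   numeric feature columns.
#' @param test Tibble with the same feature columns.
#' @param features Feature column names (default: specimen-averaged
#'   volume, ellipticity, tortuosity).
#' @return Matrix of per-class scores (rows = test rows, columns = classes,
#'   rows sum to 1).
#' @export
baseline_classifier <- function(train, test,
                                features = c("volume_um3", "ellipticity_prolate",
                                             "tortuosity")) {
  classes <- sort(unique(train$class_label))
  if (length(classes) < 2) stop("need >= 2 classes in the training fold", call. = FALSE)
  X <- as.matrix(train[, features])
  mu <- colMeans(X); sdv <- pmax(apply(X, 2, stats::sd), 1e-9)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  cent <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(Xs[train$class_label == cl, , drop = FALSE])
  }))
  Ts <- sweep(sweep(as.matrix(test[, features]), 2, mu), 2, sdv, `/`)
  D <- vapply(seq_along(classes), function(k) {
    sqrt(rowSums(sweep(Ts, 2, cent[k, ])^2))
  }, numeric(nrow(Ts)))
  D <- matrix(D, nrow = nrow(Ts))
  S <- exp(-D)
  S <- S / rowSums(S)
  colnames(S) <- classes
  S
}

#' Cross-validated baseline evaluation over a cohort
#'
#' Specimen-averaged morphometric features are split by
#' [stratified_group_kfold()]; in each fold the [baseline_classifier()] is
#' fit on the training specimens only and scored on the held-out ones, and
#' the pooled out-of-fold predictions are summarized by
#' [evaluate_classification()].
#'
#' @param cohort Cohort tibble (per-crypt rows with `specimen_id`, `group`
#'   and morphometric columns).
#' @param k Folds (default 10, capped at the number of specimens).
#' @param features Feature columns after specimen averaging.
#' @return A `metrics_report`.
#' @export
crossval_baseline <- function(cohort, k = 10,
                              features = c("volume_um3", "ellipticity_prolate",
                                           "tortuosity")) {
  spec <- cohort |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(features), mean), .groups = "drop") |>
    dplyr::rename(class_label = "group")
  k <- min(k, nrow(spec))
  folded <- stratified_group_kfold(spec, k)
  preds <- character(nrow(spec))
  scores <- matrix(NA_real_, nrow(spec), length(unique(spec$class_label)),
                   dimnames = list(NULL, sort(unique(spec$class_label))))
  for (f in sort(unique(folded$fold))) {
    te <- folded$fold == f
    S <- baseline_classifier(folded[!te, ], folded[te, ], features)
    scores[te, colnames(S)] <- S
    preds[te] <- colnames(S)[max.col(S, ties.method = "first")]
  }
  evaluate_classification(spec$class_label, preds, scores)
}
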