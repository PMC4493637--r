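#' Confusion-matrix performance metrics
#'
#' Computes the four standard two-class measures from confusion counts:
#' sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+FP+FN+TN)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When the
#' MCC denominator is zero (a degenerate margin) the MCC is reported as 0 by
#' convention, with a message.
#'
#' @param tp,fp,fn,tn Confusion counts (non-negative).
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`, `sn`, `sp`,
#'   `acc`, `mcc`.
#' @examples
#' compute_metrics(tp = 8, fp = 3, fn = 2, tn = 7)
#' @export
compute_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  if (total == 0) {
    abort("Confusion counts are all zero", class = "phossite_data_error")
  }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) {
    inform("MCC denominator is zero; reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- (tp * tn - fp * fn) / denom
  }
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    acc = (tp + tn) / total,
    mcc = mcc
  )
}

#' @rdname compute_metrics
#' @param truth,predicted Label vectors (`positive`/`negative`) of equal
#'   length; `metrics_from_labels()` tabulates them into confusion counts
#'   first.
#' @export
metrics_from_labels <- function(truth, predicted) {
  cc <- confusion_counts(truth, predicted)
  compute_metrics(cc$tp, cc$fp, cc$fn, cc$tn)
}

confusion_counts <- function(truth, predicted) {
  tibble(
    tp = sum(truth == "positive" & predicted == "positive"),
    fp = sum(truth == "negative" & predicted == "positive"),
    fn = sum(truth == "positive" & predicted == "negative"),
    tn = sum(truth == "negative" & predicted == "negative")
  )
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps a threshold over every distinct score (tied scores collapse into
#' one operating point) and reports sensitivity against `1 - specificity`,
#' anchored at (0, 0) and (1, 1). The AUC is the trapezoidal area under
#' these points, which equals the tie-corrected rank-sum (Mann-Whitney)
#' probability that a random positive outscores a random negative.
#'
#' @param scores Numeric decision scores (larger = more positive-like).
#' @param labels Class labels (`positive`/`negative`), both present.
#' @return A tibble with columns `threshold`, `fpr` (1 - specificity) and
#'   `tpr` (sensitivity), with the AUC attached as attribute `"auc"`.
#' @seealso [roc_auc()]
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(CLASS_LEVELS %in% labels)) {
    abort("ROC needs both classes among the labels",
      class = "phossite_data_error"
    )
  }
  np <- sum(labels == "positive")
  nn <- sum(labels == "negative")
  ord <- order(-scores)
  s <- scores[ord]
  pos <- labels[ord] == "positive"
  cum_tp <- cumsum(pos)
  cum_fp <- cumsum(!pos)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / np)
  fpr <- c(0, cum_fp[last_of_tie] / nn)
  thr <- c(Inf, s[last_of_tie])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  out <- tibble(threshold = thr, fpr = fpr, tpr = tpr)
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_curve
#' @return `roc_auc()` returns the AUC as a single number.
#' @export
roc_auc <- function(scores, labels) {
  attr(roc_curve(scores, labels), "auc")
}

# Stratified fold assignment: shuffles each class and deals fold ids
# round-robin, so per-fold class proportions are within one instance of the
# global proportions.
assign_folds <- function(labels, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      abort(
        paste0(
          "Class '", cl, "' has fewer fragments (", length(idx),
          ") than folds (", folds, ")"
        ),
        class = "phossite_data_error"
      )
    }
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Assigns fragments to stratified folds, then for each fold fits the whole
#' pipeline (encoding references, feature scaler, relief-F selection and
#' classifier) on the training folds only and scores the held-out fold.
#' KNN-containing encodings use the fold-training fragments as references
#' with self-exclusion during training. Confusion counts are pooled across
#' folds for the headline (micro-averaged) metrics; per-fold metrics are
#' kept alongside.
#'
#' @param fragments Labeled fragment tibble.
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling fold assignment and classifier fits.
#' @param threshold Decision threshold (`NULL` = family default).
#' @inheritParams phossite
#' @param ... Further arguments passed to [phossite()].
#' @return A `phossite_cv` object: pooled `metrics` (one-row tibble),
#'   `fold_metrics`, `per_residue` metrics, `roc` points, `auc`, and the
#'   per-fragment `scores` tibble.
#' @export
cross_validate <- function(fragments, scheme = "AF-CKSAAP",
                           classifier = "svm", folds = 10L, seed = 1L,
                           threshold = NULL, ...) {
  check_fragments(fragments, require_label = TRUE)
  fold_id <- assign_folds(fragments$label, folds, seed = seed)

  scored <- vector("list", folds)
  fold_metrics <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- fragments[fold_id != f, ]
    test <- fragments[fold_id == f, ]
    model <- phossite(train,
      scheme = scheme, classifier = classifier,
      seed = seed, threshold = threshold, ...
    )
    pred <- predict(model, test)
    pred$fold <- f
    scored[[f]] <- pred
    fold_metrics[[f]] <- mutate(
      metrics_from_labels(pred$label, pred$label_pred),
      fold = f, .before = 1
    )
  }
  scored <- bind_rows(scored)
  pooled <- metrics_from_labels(scored$label, scored$label_pred)
  roc <- roc_curve(scored$score, scored$label)

  structure(
    list(
      metrics = pooled,
      fold_metrics = bind_rows(fold_metrics),
      per_residue = per_residue_metrics(scored),
      roc = roc,
      auc = attr(roc, "auc"),
      scores = scored,
      config = list(
        scheme = scheme, classifier = classifier, folds = folds, seed = seed
      )
    ),
    class = "phossite_cv"
  )
}

per_residue_metrics <- function(scored) {
  res <- lapply(intersect(c("S", "T", "Y"), unique(scored$residue)), function(r) {
    sub <- scored[scored$residue == r, ]
    if (!all(CLASS_LEVELS %in% sub$label)) {
      cc <- confusion_counts(sub$label, sub$label_pred)
      m <- suppressMessages(compute_metrics(cc$tp, cc$fp, cc$fn, cc$tn))
    } else {
      m <- metrics_from_labels(sub$label, sub$label_pred)
    }
    mutate(m, residue = r, .before = 1)
  })
  bind_rows(res)
}

#' Evaluate a trained predictor on an independent test set
#'
#' Guards against train/test contamination by refusing any test fragment
#' whose `(protein_id, position)` key appears among the model's training
#' fragments, then scores the test set once and reports overall and
#' per-residue metrics, ROC points and AUC.
#'
#' @param object A `phossite_model`.
#' @param fragments Labeled test fragment tibble, disjoint from training.
#' @param threshold Decision threshold (`NULL` = model default).
#' @return A `phossite_eval` object with the same fields as a
#'   `phossite_cv` (minus fold metrics).
#' @export
evaluate_predictor <- function(object, fragments, threshold = NULL) {
  stopifnot(inherits(object, "phossite_model"))
  check_fragments(fragments, require_label = TRUE)
  overlap <- intersect(fragment_keys(fragments), object$training_keys)
  if (length(overlap)) {
    abort(
      paste0(
        length(overlap), " test fragment(s) overlap the training set: ",
        paste(head(overlap, 5), collapse = ", "),
        if (length(overlap) > 5) ", ..." else ""
      ),
      class = "phossite_data_error"
    )
  }
  pred <- predict(object, fragments, threshold = threshold)
  metrics <- metrics_from_labels(pred$label, pred$label_pred)
  roc <- roc_curve(pred$score, pred$label)
  structure(
    list(
      metrics = metrics,
      per_residue = per_residue_metrics(pred),
      roc = roc,
      auc = attr(roc, "auc"),
      scores = pred,
      config = list(
        scheme = object$scheme, classifier = object$classifier,
        threshold = threshold %||% object$threshold
      )
    ),
    class = "phossite_eval"
  )
}

#' @export
print.phossite_cv <- function(x, ...) {
  cat(
    "<phossite_cv> ", x$config$classifier, "+", x$config$scheme, ", ",
    x$config$folds, "-fold\n",
    sep = ""
  )
  print(as.data.frame(x$metrics), row.names = FALSE)
  cat("AUC:", round(x$auc, 4), "\n")
  invisible(x)
}

#' @export
print.phossite_eval <- function(x, ...) {
  cat(
    "<phossite_eval> ", x$config$classifier, "+", x$config$scheme, "\n",
    sep = ""
  )
  print(as.data.frame(x$metrics), row.names = FALSE)
  cat("AUC:", round(x$auc, 4), "\n")
  invisible(x)
}

#' Tidy cross-validation results
#'
#' @param x A `phossite_cv` object.
#' @param ... Unused.
#' @return Per-fold metrics, one row per fold.
#' @export
tidy.phossite_cv <- function(x, ...) {
  x$fold_metrics
}

#' One-row summary of cross-validation results
#'
#' @param x A `phossite_cv` object.
#' @param ... Unused.
#' @return A one-row tibble with pooled Sn, Sp, ACC, MCC and AUC.
#' @export
glance.phossite_cv <- function(x, ...) {
  mutate(
    x$metrics,
    auc = x$auc,
    scheme = x$config$scheme, classifier = x$config$classifier
  )
}

#' @export
tidy.phossite_eval <- function(x, ...) {
  x$per_residue
}

#' @export
glance.phossite_eval <- function(x, ...) {
  mutate(
    x$metrics,
    auc = x$auc,
    scheme = x$config$scheme, classifier = x$config$classifier
  )
}

#' ROC plot for cross-validation or independent-test results
#'
#' @param object A `phossite_cv` or `phossite_eval` object.
#' @param ... Unused.
#' @return A ggplot object: sensitivity against 1 - specificity with the
#'   chance diagonal.
#' @export
autoplot.phossite_cv <- function(object, ...) {
  plot_roc(object)
}

#' @rdname autoplot.phossite_cv
#' @export
autoplot.phossite_eval <- function(object, ...) {
  plot_roc(object)
}

plot_roc <- function(object) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60"
    ) +
    ggplot2::geom_path(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = paste0(
        object$config$classifier, " + ", object$config$scheme,
        "  (AUC = ", sprintf("%.3f", object$auc), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
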