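#' Build the per-subject classifier feature table
#'
#' The feature vector is the mean beta power of the accepted epochs in each
#' of the four video segments plus the session total mean beta, all
#' standardized (zero mean, unit variance) across the cohort. The label is
#' `pass` when the task score reaches the pass mark. A segment left with no
#' accepted epochs falls back to the subject's session mean so the feature
#' matrix has no missing values.
#'
#' @param processed Combined epoch table from [process_epochs()] (rows for
#'   all subjects).
#' @param summaries Normalized summary table from [normalize_cohort()].
#' @param annotation The [session_annotation()].
#' @param cohort_table Data frame with `subject_id` and `score`.
#' @param cfg A [processing_config()].
#' @param pass_mark Pass threshold on the task score (default 5).
#' @return A tibble with `subject_id`, `label` (`"pass"`/`"fail"`) and
#'   standardized feature columns `seg1..seg4`, `total`.
#' @export
make_features <- function(processed, summaries, annotation, cohort_table,
                          cfg = processing_config(), pass_mark = 5) {
  video <- annotation[annotation$label == "video", , drop = FALSE]
  video$segment <- paste0("seg", seq_len(nrow(video)))
  dur <- cfg$epoch_len / cfg$fs
  kept <- processed[processed$status == "ok", , drop = FALSE]
  kept$segment <- vapply(kept$start_s, function(s) {
    hit <- which(s >= video$start_s & (s + dur) <= video$end_s)
    if (length(hit)) video$segment[hit[1]] else NA_character_
  }, character(1))
  kept <- kept[!is.na(kept$segment), , drop = FALSE]
  seg_means <- kept |>
    dplyr::group_by(.data$subject_id, .data$segment) |>
    dplyr::summarise(m = mean(.data$beta_power), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "m")
  for (s in video$segment) {
    if (!s %in% names(seg_means)) seg_means[[s]] <- NA_real_
  }
  out <- summaries |>
    dplyr::filter(.data$valid) |>
    dplyr::select("subject_id", total = "total_mean_beta") |>
    dplyr::left_join(seg_means, by = "subject_id") |>
    dplyr::left_join(cohort_table[, c("subject_id", "score")],
                     by = "subject_id")
  feat_cols <- c(video$segment, "total")
  for (s in video$segment) {
    out[[s]] <- ifelse(is.na(out[[s]]), out$total, out[[s]])
  }
  for (f in feat_cols) {
    out[[f]] <- as.vector(scale(out[[f]]))
  }
  tibble(
    subject_id = out$subject_id,
    label = ifelse(out$score >= pass_mark, "pass", "fail"),
    !!!setNames(purrr::map(feat_cols, function(f) out[[f]]), feat_cols)
  )
}

#' Default hyperparameter grid for the pass/fail perceptron
#'
#' Hidden-layer width and L2 weight decay of the single-hidden-layer
#' multilayer perceptron explored by grid search.
#'
#' @return A tibble with columns `size` and `decay`.
#' @export
default_grid <- function() {
  tidyr::expand_grid(size = c(2L, 4L, 8L), decay = c(1e-4, 1e-3, 1e-2))
}

# Fit one MLP and return the predicted pass probabilities for newdata.
fit_predict_mlp <- function(train, test, feat_cols, size, decay,
                            maxit = 300) {
  X <- as.matrix(train[, feat_cols])
  y <- as.numeric(train$label == "pass")
  fit <- nnet::nnet(X, y, size = size, decay = decay, maxit = maxit,
                    entropy = TRUE, trace = FALSE)
  as.vector(predict(fit, as.matrix(test[, feat_cols])))
}

#' Leave-one-out pass/fail prediction with nested grid search
#'
#' Runs n leave-one-out iterations. In each, the held-out subject plays the
#' test set; hyperparameters are selected by an inner 5-fold
#' cross-validation (mean binomial log loss) on the remaining subjects only,
#' then the perceptron is refit on all of them and the held-out subject's
#' pass probability recorded. The held-out subject never influences its own
#' fold's scaling, selection or fit.
#'
#' @param rows Feature table from [make_features()] (columns `subject_id`,
#'   `label`, features).
#' @param grid Hyperparameter tibble (`size`, `decay`); see
#'   [default_grid()].
#' @param seed Integer seed driving fold assignment and weight
#'   initialization; a fixed seed gives identical predictions.
#' @param inner_k Inner folds for the grid search (default 5).
#' @return A tibble of class `beta_loocv` with `subject_id`, `label`,
#'   `prob` (predicted pass probability) and the per-fold chosen
#'   hyperparameters in the `hyperparams` attribute.
#' @export
loocv_predict <- function(rows, grid = default_grid(), seed = 1L,
                          inner_k = 5) {
  n <- nrow(rows)
  if (n < 3) abort("Leave-one-out needs at least 3 subjects.")
  if (length(unique(rows$label)) < 2) {
    abort("Both classes must be present to train the classifier.")
  }
  feat_cols <- setdiff(names(rows), c("subject_id", "label"))
  probs <- numeric(n)
  chosen <- vector("list", n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      train <- rows[-i, , drop = FALSE]
      test <- rows[i, , drop = FALSE]
      k <- min(inner_k, nrow(train))
      folds <- sample(rep(seq_len(k), length.out = nrow(train)))
      losses <- purrr::pmap_dbl(grid, function(size, decay) {
        ll <- vapply(seq_len(k), function(f) {
          tr <- train[folds != f, , drop = FALSE]
          va <- train[folds == f, , drop = FALSE]
          if (length(unique(tr$label)) < 2) return(NA_real_)
          p <- fit_predict_mlp(tr, va, feat_cols, size, decay)
          p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
          yv <- as.numeric(va$label == "pass")
          -mean(yv * log(p) + (1 - yv) * log(1 - p))
        }, numeric(1))
        mean(ll, na.rm = TRUE)
      })
      # all-NA losses can only happen when every inner training split is
      # single-class (tiny cohorts); fall back to the first grid row
      best <- if (all(is.na(losses))) 1L else which.min(losses)
      chosen[[i]] <- tibble(fold = i, size = grid$size[best],
                            decay = grid$decay[best])
      probs[i] <- fit_predict_mlp(train, test, feat_cols,
                                  grid$size[best], grid$decay[best])
    }
  })
  out <- tibble(subject_id = rows$subject_id, label = rows$label,
                prob = probs)
  class(out) <- c("beta_loocv", class(out))
  attr(out, "hyperparams") <- dplyr::bind_rows(chosen)
  out
}

# Truncate to 2 decimals: the convention that reproduces the platform's
# reported metric digits (e.g. 14/19 = 0.7368 -> 0.73).
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

#' Evaluate pooled predictions: confusion matrix, metrics, ROC and AUC
#'
#' Thresholds the pooled pass probabilities at `threshold` for the confusion
#' matrix ("pass" is the positive class) and computes recall, precision,
#' accuracy and F1, both at full precision and truncated to the two decimals
#' used in reports. The ROC curve sweeps every distinct probability
#' cut-point; the AUC is the trapezoidal area.
#'
#' @param predictions A `beta_loocv` tibble (or any data frame with `prob`
#'   and `label`), or a numeric probability vector.
#' @param labels Labels (`"pass"`/`"fail"`, logical, or 0/1) when
#'   `predictions` is a bare vector.
#' @param threshold Probability cut for the confusion matrix (default 0.5).
#' @return An object of class `beta_clf_report` with `confusion` (TP, FP,
#'   FN, TN), `metrics` (exact), `reported` (2-decimal truncation),
#'   `roc` (tibble of FPR/TPR points) and `auc`.
#' @examples
#' evaluate_predictions(c(0.9, 0.2, 0.7, 0.4),
#'                      c("pass", "fail", "pass", "fail"))
#' @export
evaluate_predictions <- function(predictions, labels = NULL,
                                 threshold = 0.5) {
  if (is.data.frame(predictions)) {
    labels <- predictions$label
    prob <- predictions$prob
    hp <- attr(predictions, "hyperparams")
  } else {
    prob <- predictions
    hp <- NULL
  }
  if (length(prob) != length(labels)) {
    abort("`predictions` and `labels` must have equal length.")
  }
  if (any(prob < 0 | prob > 1)) abort("Probabilities must lie in [0, 1].")
  pos <- to_positive(labels)
  pred <- prob >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  metrics <- c(
    recall = tp / (tp + fn),
    precision = tp / (tp + fp),
    accuracy = (tp + tn) / length(pos),
    f1 = 2 * tp / (2 * tp + fp + fn)
  )
  roc <- roc_points(prob, pos)
  structure(
    list(
      confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
      metrics = metrics,
      reported = trunc2(metrics),
      roc = roc,
      auc = trapezoid_auc(roc),
      threshold = threshold,
      n = length(pos),
      hyperparams = hp
    ),
    class = "beta_clf_report"
  )
}

#' Confusion-matrix metrics from printed counts
#'
#' Computes the report metrics directly from a confusion matrix (with
#' "pass" as positive), for checking published tables: recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy `(TP+TN)/n` and
#' F1 `2TP/(2TP+FP+FN)`, each also truncated to two decimals.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return A tibble with `metric`, `value` and `reported` columns.
#' @examples
#' confusion_metrics(14, 2, 5, 13)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  metrics <- c(
    recall = tp / (tp + fn),
    precision = tp / (tp + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    f1 = 2 * tp / (2 * tp + fp + fn)
  )
  tibble(metric = names(metrics), value = unname(metrics),
         reported = trunc2(unname(metrics)))
}

to_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "pass"
}

# ROC points over all distinct probability cut-points (descending), from
# (0,0) to (1,1).
roc_points <- function(prob, pos) {
  cuts <- c(Inf, sort(unique(prob), decreasing = TRUE))
  np <- sum(pos); nn <- sum(!pos)
  tibble(
    cut = cuts,
    tpr = vapply(cuts, function(c) sum(prob >= c & pos) / np, numeric(1)),
    fpr = vapply(cuts, function(c) sum(prob >= c & !pos) / nn, numeric(1))
  )
}

trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.beta_clf_report <- function(x, ...) {
  cat("<beta_clf_report> n =", x$n, "\n")
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d (threshold %.2f)\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TN"], x$threshold))
  cat(sprintf(
    "  recall %.2f | precision %.2f | accuracy %.2f | F1 %.2f | AUC %.2f\n",
    x$reported["recall"], x$reported["precision"], x$reported["accuracy"],
    x$reported["f1"], trunc2(x$auc)
  ))
  invisible(x)
}

#' @export
tidy.beta_clf_report <- function(x, ...) {
  tibble(
    metric = c(names(x$metrics), "auc"),
    value = c(unname(x$metrics), x$auc),
    reported = c(unname(x$reported), trunc2(x$auc))
  )
}

#' @export
glance.beta_clf_report <- function(x, ...) {
  tibble(
    n = x$n, TP = x$confusion["TP"], FP = x$confusion["FP"],
    FN = x$confusion["FN"], TN = x$confusion["TN"],
    accuracy = x$metrics["accuracy"], auc = x$auc,
    threshold = x$threshold
  )
}

#' @export
autoplot.beta_clf_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(color = "steelblue", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}
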