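#' Stratified train/test split
#'
#' Partitions a cohort into disjoint, exhaustive training and test subsets.
#' With stratification each class contributes `floor(n_c * train_fraction)`
#' samples to training, and any remaining seats (to reach
#' `floor(n * train_fraction)` overall) go to the classes with the largest
#' fractional parts; at 90 samples split 7:3 this yields 63 training and 27
#' test samples, 21/9 per origin. The within-class shuffle is seeded.
#'
#' @param cohort A `voc_cohort` tibble.
#' @param train_fraction Fraction of samples assigned to training (0, 1).
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify by origin (default `TRUE`).
#' @return A list with `train` and `test` cohort tibbles and the integer
#'   `train_idx` / `test_idx` row indices.
#' @export
#' @examples
#' sp <- stratified_split(generate_cohort(voc_reference(), seed = 1), seed = 2)
#' nrow(sp$train); nrow(sp$test)
stratified_split <- function(cohort, train_fraction = 0.7, seed = NULL,
                             stratified = TRUE) {
  check_number(train_fraction, "train_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- nrow(cohort)
  labels <- cohort$origin
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L)) {
    stop_kelp("every class needs at least 2 samples to split",
              class = "kelptrace_argument_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (stratified) {
    counts <- vapply(classes, function(g) sum(labels == g), integer(1L))
    base <- floor(counts * train_fraction)
    target <- floor(n * train_fraction)
    extra <- target - sum(base)
    if (extra > 0L) {
      frac <- counts * train_fraction - base
      bump <- order(frac, decreasing = TRUE)[seq_len(extra)]
      base[bump] <- base[bump] + 1L
    }
    train_idx <- integer(0)
    for (i in seq_along(classes)) {
      rows <- which(labels == classes[i])
      rows <- rows[sample.int(length(rows))]
      train_idx <- c(train_idx, rows[seq_len(base[i])])
    }
    train_idx <- sort(train_idx)
  } else {
    train_idx <- sort(sample.int(n, floor(n * train_fraction)))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(
    train = cohort[train_idx, , drop = FALSE],
    test = cohort[test_idx, , drop = FALSE],
    train_idx = train_idx, test_idx = test_idx
  )
}

#' Fit / apply per-feature z-score standardization
#'
#' `fit_scaler()` learns per-feature location (mean) and scale (population
#' standard deviation, i.e. divisor n) from the training rows only;
#' `apply_scaler()` transforms any cohort with those frozen parameters, so
#' test data never influence the scaling (no fit-on-test entry point
#' exists). Zero-variance features transform to 0, with a warning at fit
#' time.
#'
#' @param train A training `voc_cohort` tibble.
#' @return `fit_scaler()` returns an object of class `voc_scaler` holding
#'   `mu`, `sigma`, the feature ids, and the SD convention used.
#' @export
fit_scaler <- function(train) {
  mat <- cohort_matrix(train)
  if (nrow(mat) == 0L) {
    stop_kelp("cannot fit a scaler on an empty training set",
              class = "kelptrace_argument_error")
  }
  mu <- colMeans(mat)
  sigma <- sqrt(colMeans(sweep(mat, 2L, mu, "-")^2))
  if (any(sigma == 0)) {
    rlang::warn(sprintf("%d constant training feature(s) will standardize to 0",
                        sum(sigma == 0)))
  }
  structure(list(mu = mu, sigma = sigma, feature_ids = colnames(mat),
                 sd_convention = "population (divisor n)"),
            class = "voc_scaler")
}

#' @param scaler A `voc_scaler` from [fit_scaler()].
#' @param data A cohort tibble or numeric matrix with the scaler's features.
#' @return `apply_scaler()` returns `data` with feature columns standardized.
#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, data) {
  if (is.data.frame(data)) {
    out <- data
    for (j in scaler$feature_ids) {
      s <- scaler$sigma[[j]]
      out[[j]] <- if (s > 0) (data[[j]] - scaler$mu[[j]]) / s else
        rep(0, nrow(data))
    }
    return(out)
  }
  mat <- data[, scaler$feature_ids, drop = FALSE]
  centered <- sweep(mat, 2L, scaler$mu, "-")
  safe_sigma <- ifelse(scaler$sigma > 0, scaler$sigma, 1)
  scaled <- sweep(centered, 2L, safe_sigma, "/")
  scaled[, scaler$sigma == 0] <- 0
  scaled
}

# One-vs-rest ROC by threshold sweep over one class's score column.
# Ties in score produce diagonal segments, so the trapezoidal AUC equals the
# Mann-Whitney statistic with half credit for ties.
roc_points <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  positive <- positive[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(scores))
  tp <- cumsum(positive)
  fp <- cumsum(!positive)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tibble::tibble(
    threshold = c(Inf, scores[last]),
    tpr = c(0, tp[last] / max(n_pos, 1L)),
    fpr = c(0, fp[last] / max(n_neg, 1L))
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
}

#' Evaluate class-probability predictions
#'
#' Builds the confusion matrix (argmax decision, ties to the lowest class
#' index) and the standard per-class one-vs-rest metrics — accuracy
#' ((TP + TN) / total), recall (TP / (TP + FN)), precision (TP / (TP + FP)),
#' F1 (harmonic mean) — together with macro averages, overall accuracy
#' (trace of the confusion matrix over n), and per-class one-vs-rest ROC
#' curves with trapezoidal AUC.
#'
#' @param y_true Integer true labels (0-based).
#' @param probs Matrix or tibble of class probabilities (rows sum to 1).
#' @param n_classes Number of classes (defaults to `ncol(probs)`).
#' @return An object of class `origin_eval`: list with `confusion` (rows =
#'   truth), `metrics` (per-class tibble), `accuracy`, `macro` (named
#'   vector), `roc` (long tibble of per-class curves) and `auc` (named
#'   vector).
#' @export
evaluate_predictions <- function(y_true, probs, n_classes = NULL) {
  if (is.data.frame(probs)) probs <- as.matrix(probs)
  if (length(y_true) != nrow(probs)) {
    stop_kelp("length(y_true) must equal nrow(probs)",
              class = "kelptrace_argument_error")
  }
  if (is.null(n_classes)) n_classes <- ncol(probs)
  y_pred <- max.col(probs, ties.method = "first") - 1L

  confusion <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    confusion[y_true[i] + 1L, y_pred[i] + 1L] <-
      confusion[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  class_names <- names(.kelp_origins)[seq_len(n_classes)]
  dimnames(confusion) <- list(true = class_names, predicted = class_names)

  n <- length(y_true)
  per_class <- purrr::map_dfr(seq_len(n_classes), function(c1) {
    tp <- confusion[c1, c1]
    fn <- sum(confusion[c1, ]) - tp
    fp <- sum(confusion[, c1]) - tp
    tn <- n - tp - fn - fp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(
      class = class_names[c1], tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy_ovr = (tp + tn) / n, precision = precision, recall = recall,
      f1 = f1
    )
  })

  roc <- purrr::map_dfr(seq_len(n_classes), function(c1) {
    pts <- roc_points(probs[, c1], y_true == c1 - 1L)
    dplyr::mutate(pts, class = class_names[c1], .before = 1L)
  })
  auc <- vapply(class_names, function(cl) {
    pts <- roc[roc$class == cl, ]
    trapezoid_auc(pts$fpr, pts$tpr)
  }, numeric(1L))

  structure(
    list(
      confusion = confusion,
      metrics = per_class,
      accuracy = sum(diag(confusion)) / n,
      macro = c(precision = mean(per_class$precision),
                recall = mean(per_class$recall),
                f1 = mean(per_class$f1)),
      roc = roc,
      auc = auc,
      n_test = n
    ),
    class = "origin_eval"
  )
}

#' @export
print.origin_eval <- function(x, ...) {
  cat(sprintf("Origin classification on %d samples: accuracy %.1f%%, macro F1 %.1f%%\n",
              x$n_test, 100 * x$accuracy, 100 * x$macro[["f1"]]))
  cat(sprintf("per-class AUC: %s\n",
              paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", ")))
  print(x$confusion)
  invisible(x)
}

#' Per-class metrics of an evaluation
#' @param x An `origin_eval`.
#' @param ... Unused.
#' @method tidy origin_eval
#' @export
tidy.origin_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, auc = unname(x$auc[.data$class]))
}

#' One-row evaluation summary
#' @param x An `origin_eval`.
#' @param ... Unused.
#' @method glance origin_eval
#' @export
glance.origin_eval <- function(x, ...) {
  tibble::tibble(
    n_test = x$n_test,
    accuracy = x$accuracy,
    macro_precision = x$macro[["precision"]],
    macro_recall = x$macro[["recall"]],
    macro_f1 = x$macro[["f1"]],
    mean_auc = mean(x$auc),
    min_auc = min(x$auc)
  )
}

#' Serialize an evaluation report to JSON
#' @param eval_report An `origin_eval`.
#' @param path Output path.
#' @export
write_evaluation <- function(eval_report, path) {
  jsonlite::write_json(
    list(
      confusion = unclass(eval_report$confusion),
      accuracy = eval_report$accuracy,
      macro = as.list(eval_report$macro),
      per_class = eval_report$metrics,
      auc = as.list(eval_report$auc),
      roc = eval_report$roc,
      n_test = eval_report$n_test
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
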