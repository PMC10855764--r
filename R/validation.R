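#' Confusion counts for a one-vs-rest dichotomy
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The class treated as positive.
#' @return Object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`. Counts are kept as doubles so that averaged matrices (as reported
#'   across cross-validation repetitions) remain representable.
#' @export
confusion <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!positive %in% c(truth, predicted)) {
    stop("positive class ", positive, " absent from the label alphabet",
         call. = FALSE)
  }
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(list(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
                 fp = sum(!tpos & ppos), fn = sum(tpos & !ppos)),
            class = "confusion_counts")
}

confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Model efficiency: geometric mean of sensitivity and specificity
#'
#' @param sensitivity,specificity Values in [0, 1].
#' @return `sqrt(sensitivity * specificity)`, in [0, 1].
#' @examples
#' efficiency(0.990, 0.818)  # 0.900 to 3 decimals
#' @export
efficiency <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sqrt(sensitivity * specificity)
}

#' Precision (positive predictive value)
#'
#' The fraction of samples classified as positive that truly are:
#' `TP / (TP + FP)`. Undefined (returned as `NA`) when no sample was
#' classified positive -- never reported as 0.
#'
#' @param counts A `confusion_counts`.
#' @return Precision in [0, 1], or `NA_real_` if `TP + FP == 0`.
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + counts$fp
  if (denom == 0) return(NA_real_)
  counts$tp / denom
}

#' Matthews correlation coefficient
#'
#' Balanced binary-classification correlation using all four confusion cells:
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in [-1, 1].
#' Undefined (`NA`) when any marginal is zero.
#'
#' @param counts A `confusion_counts`.
#' @return MCC in [-1, 1] or `NA_real_`.
#' @export
matthews <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (any(marg == 0)) return(NA_real_)
    (tp * tn - fp * fn) / sqrt(prod(marg))
  })
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`;
#'   entries with a zero denominator are `NA`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    total <- tp + tn + fp + fn
    c(accuracy = (tp + tn) / total,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
}

#' Cross-validated regression diagnostics: RMSECV, Q2 and discriminant Q2
#'
#' For a 0/1 class indicator `y` and its cross-validated continuous
#' predictions: RMSECV is the root mean squared prediction error; Q2 is
#' `1 - PRESS / TSS`; DQ2 (discriminant Q2) is identical except that residuals
#' are zeroed when the prediction already lies beyond its class label
#' (prediction above 1 for a positive, below 0 for a negative) -- a classifier
#' is not penalized for over-committing to the correct side. DQ2 >= Q2 always.
#'
#' @param y Numeric 0/1 indicator.
#' @param y_hat Cross-validated continuous predictions, same length.
#' @return Named numeric vector `c(rmsecv, q2, dq2)`; `q2`/`dq2` are `NA` when
#'   the indicator is constant.
#' @export
regression_cv_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), all(y %in% c(0, 1)))
  res <- y - y_hat
  rmsecv <- sqrt(mean(res^2))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    return(c(rmsecv = rmsecv, q2 = NA_real_, dq2 = NA_real_))
  }
  res_d <- res
  res_d[y == 1 & y_hat > 1] <- 0
  res_d[y == 0 & y_hat < 0] <- 0
  c(rmsecv = rmsecv,
    q2 = 1 - sum(res^2) / tss,
    dq2 = 1 - sum(res_d^2) / tss)
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one, with ties counted one half -- the Mann-Whitney
#' formulation, computed from midranks.
#'
#' @param y Numeric 0/1 indicator (both classes present).
#' @param scores Continuous classifier scores, higher = more positive.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(y, scores) {
  stopifnot(length(y) == length(scores), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC undefined: one class absent", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full diagnostic panel for one class
#'
#' @param y 0/1 indicator of membership in the class.
#' @param scores Cross-validated continuous predicted indicator.
#' @param threshold Hard-label threshold on the indicator.
#' @param hard Optional 0/1 hard assignments overriding the thresholding
#'   (e.g. derived from a multi-class argmax).
#' @return Named numeric vector with rmsecv, q2, dq2, accuracy, sensitivity,
#'   specificity, efficiency, precision, matthews, auroc.
#' @export
diagnostic_panel <- function(y, scores, threshold = 0.5, hard = NULL) {
  reg <- regression_cv_metrics(y, scores)
  pred <- if (is.null(hard)) as.numeric(scores > threshold) else as.numeric(hard)
  cc <- confusion_counts(tp = sum(y == 1 & pred == 1),
                         tn = sum(y == 0 & pred == 0),
                         fp = sum(y == 0 & pred == 1),
                         fn = sum(y == 1 & pred == 0))
  cm <- classification_metrics(cc)
  eff <- if (anyNA(cm[c("sensitivity", "specificity")])) NA_real_ else
    efficiency(cm[["sensitivity"]], cm[["specificity"]])
  c(reg,
    cm,
    efficiency = eff,
    precision = precision(cc),
    matthews = matthews(cc),
    auroc = auroc(y, scores))
}

#' Exact binomial reference for misclassification counts
#'
#' Under no class structure, the number of misclassified samples out of n is
#' binomial with per-sample misclassification probability p (0.5 for a
#' balanced two-class problem).
#'
#' @param n Number of classified samples.
#' @param p Per-sample misclassification probability.
#' @return List with `counts` (0..n), `pmf` (exact binomial mass), `mean`.
#' @export
binomial_reference <- function(n, p = 0.5) {
  stopifnot(n >= 1, p > 0, p < 1)
  counts <- 0:n
  list(counts = counts, pmf = stats::dbinom(counts, n, p), mean = n * p)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds
stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has ", length(idx),
           " samples, fewer than ", k, " folds", call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Inner cross-validation on one training partition: k-fold CV of a single
# binary PLS1 response, returning the inner Q2 per candidate number of LVs.
# One NIPALS fit per fold yields cumulative predictions for every LV count.
inner_q2 <- function(X, y, k, max_lv) {
  fold <- stratified_folds(ifelse(y == 1, "pos", "neg"), k)
  press <- numeric(max_lv)
  used_lv <- max_lv
  preds <- matrix(NA_real_, length(y), max_lv)
  for (f in seq_len(k)) {
    tr <- fold != f
    sc <- autoscale_quiet(X[tr, , drop = FALSE])
    fit <- pls1_nipals(sc$values, y[tr], ncomp = max_lv)
    used_lv <- min(used_lv, fit$ncomp)
    cum <- pls1_predict_cum(fit, apply_scaling(sc, X[!tr, , drop = FALSE]))
    preds[!tr, seq_len(fit$ncomp)] <- cum
    if (fit$ncomp < max_lv) {  # carry the deepest available model forward
      preds[!tr, seq(fit$ncomp + 1L, max_lv)] <- cum[, fit$ncomp]
    }
  }
  tss <- sum((y - mean(y))^2)
  q2 <- 1 - colSums((y - preds)^2) / tss
  q2
}

autoscale_quiet <- function(X) suppressWarnings(autoscale(X))

#' Double (nested) cross-validation of PLS-DA
#'
#' Outer stratified k-fold cross-validation estimates classification
#' performance; for each outer fold, an inner k-fold cross-validation on the
#' outer-training partition alone selects the number of latent variables
#' maximizing the inner Q2 of each one-vs-rest class response. The selected
#' model is refit on the full outer-training partition and applied to the
#' held-out fold, so no held-out sample influences scaling, complexity
#' selection or fitting for its own fold. The whole procedure is repeated
#' `n_repetitions` times with fresh fold assignments and the per-class
#' diagnostic panel is aggregated as mean and median across repetitions.
#'
#' @param X Numeric predictor matrix (samples x variables), raw scale.
#' @param labels Class labels (>= 2 classes, each with >= `outer_k` members).
#' @param outer_k,inner_k Fold counts of the outer and inner loops.
#' @param n_repetitions Number of repeated outer splits.
#' @param max_lv Largest number of latent variables considered.
#' @param seed Integer seed governing all fold assignments.
#' @param threshold Hard-label threshold on the predicted indicator.
#' @return Object of class `cv_report`: `mean` and `median` (metric x class
#'   matrices), `per_repetition` (3-D array), `overall_accuracy` (per
#'   repetition, by multi-class argmax), `chosen_lv` (per repetition x outer
#'   fold x class), `classes`, `n_repetitions`.
#' @export
double_cross_validate <- function(X, labels, outer_k = 5L, inner_k = 5L,
                                  n_repetitions = 20L, max_lv = 10L,
                                  seed = 1L, threshold = 0.5) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  max_lv <- min(max_lv, ncol(X), nrow(X) - 2L)
  metrics <- c("rmsecv", "q2", "dq2", "accuracy", "sensitivity", "specificity",
               "efficiency", "precision", "matthews", "auroc")
  panel <- array(NA_real_,
                 dim = c(length(metrics), length(classes), n_repetitions),
                 dimnames = list(metrics, classes, NULL))
  overall <- numeric(n_repetitions)
  chosen <- array(NA_integer_,
                  dim = c(n_repetitions, outer_k, length(classes)),
                  dimnames = list(NULL, NULL, classes))

  withr::with_seed(seed, {
    for (r in seq_len(n_repetitions)) {
      fold <- stratified_folds(labels, outer_k)
      scores <- matrix(NA_real_, nrow(X), length(classes),
                       dimnames = list(NULL, classes))
      for (f in seq_len(outer_k)) {
        tr <- fold != f
        Xtr <- X[tr, , drop = FALSE]
        for (ci in seq_along(classes)) {
          y_tr <- as.numeric(labels[tr] == classes[ci])
          q2 <- inner_q2(Xtr, y_tr, k = inner_k, max_lv = max_lv)
          a_best <- which.max(q2)
          chosen[r, f, ci] <- a_best
          sc <- autoscale_quiet(Xtr)
          fit <- pls1_nipals(sc$values, y_tr, ncomp = a_best)
          pred <- pls1_predict_cum(fit, apply_scaling(sc, X[!tr, , drop = FALSE]))
          scores[!tr, ci] <- pred[, fit$ncomp]
        }
      }
      # hard assignment: argmax across the one-vs-rest scores for >= 3
      # classes; indicator threshold for the plain binary problem
      hard <- if (length(classes) > 2L) {
        classes[max.col(scores, ties.method = "first")]
      } else {
        ifelse(scores[, 2L] > threshold, classes[2L], classes[1L])
      }
      for (ci in seq_along(classes)) {
        panel[, ci, r] <- diagnostic_panel(as.numeric(labels == classes[ci]),
                                           scores[, ci], threshold = threshold,
                                           hard = as.numeric(hard == classes[ci]))
      }
      overall[r] <- mean(hard == labels)
    }
  })

  structure(list(mean = apply(panel, c(1, 2), mean, na.rm = TRUE),
                 median = apply(panel, c(1, 2), stats::median, na.rm = TRUE),
                 per_repetition = panel,
                 overall_accuracy = overall,
                 chosen_lv = chosen,
                 classes = classes,
                 n_repetitions = n_repetitions),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("Double cross-validation report (%d repetitions)\n",
              x$n_repetitions))
  cat("Mean across repetitions:\n")
  print(round(x$mean, digits))
  cat("Median across repetitions:\n")
  print(round(x$median, digits))
  cat(sprintf("Overall (argmax) accuracy: mean %.3f\n",
              mean(x$overall_accuracy)))
  invisible(x)
}

#' Export a cross-validation report as a flat table
#'
#' Rows are the ten diagnostics, columns the class-by-aggregate combinations
#' (mirroring a mean/median panel layout).
#'
#' @param report A `cv_report`.
#' @return Data frame with a `metric` column followed by
#'   `<class>_mean` / `<class>_median` columns.
#' @export
cv_report_table <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  out <- data.frame(metric = rownames(report$mean))
  for (cl in report$classes) {
    out[[paste0(cl, "_mean")]] <- report$mean[, cl]
    out[[paste0(cl, "_median")]] <- report$median[, cl]
  }
  out
}

#' Permutation test of PLS-DA misclassification
#'
#' Builds the empirical null distribution of the misclassified-sample count by
#' repeatedly permuting the class labels, rerunning the cross-validated
#' classifier (the same nested scheme as [double_cross_validate()] with a
#' single repetition per iteration) and counting wrong hard assignments. The
#' null is compared against the exact binomial reference with per-sample
#' misclassification probability 0.5, and the observed (unpermuted) count is
#' assigned the left-tail empirical p-value with add-one smoothing,
#' `(#\{null <= observed\} + 1) / (n_iterations + 1)`.
#'
#' @param X Predictor matrix.
#' @param labels Class labels.
#' @param n_iterations Number of label permutations (the study-scale value is
#'   30,000; the default is desk-scale).
#' @param outer_k,inner_k,max_lv Cross-validation settings, as in
#'   [double_cross_validate()].
#' @param seed Integer seed.
#' @param threshold Hard-label threshold.
#' @return Object of class `permutation_result`: `misclassified` (count per
#'   iteration), `observed` (unpermuted count), `p_value`, `n_samples`,
#'   `reference` (see [binomial_reference()]).
#' @export
permutation_test <- function(X, labels, n_iterations = 1000L,
                             outer_k = 5L, inner_k = 5L, max_lv = 10L,
                             seed = 1L, threshold = 0.5) {
  stopifnot(n_iterations >= 1L)
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- length(labels)

  run_once <- function(lab) {
    rep1 <- double_cross_validate(X, lab, outer_k = outer_k, inner_k = inner_k,
                                  n_repetitions = 1L, max_lv = max_lv,
                                  seed = sample.int(.Machine$integer.max, 1L),
                                  threshold = threshold)
    round((1 - rep1$overall_accuracy[1L]) * n)
  }

  withr::with_seed(seed, {
    observed <- run_once(labels)
    mis <- vapply(seq_len(n_iterations), function(i) {
      run_once(sample(labels))
    }, numeric(1))
  })
  p <- (sum(mis <= observed) + 1) / (n_iterations + 1)
  structure(list(misclassified = mis, observed = observed, p_value = p,
                 n_samples = n, n_iterations = n_iterations,
                 reference = binomial_reference(n, 0.5)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Permutation test: %d iterations on %d samples\n",
                     "  null misclassified: mean %.1f (binomial reference mean %.1f)\n",
                     "  observed misclassified: %d, empirical p = %.4g\n"),
              x$n_iterations, x$n_samples, mean(x$misclassified),
              x$reference$mean, x$observed, x$p_value))
  invisible(x)
}
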