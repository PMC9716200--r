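#' Confusion-matrix derived classification rates
#'
#' @param tp,fp,tn,fn non-negative confusion counts (total > 0).
#' @return list with `ppv`, `npv`, `sensitivity`, `specificity` (ratios with
#'   zero denominators returned as `NaN`), an `undefined` flag vector and the
#'   counts.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("confusion counts sum to zero", call. = FALSE)
  rate <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  rates <- c(ppv = rate(tp, fp), npv = rate(tn, fn),
             sensitivity = rate(tp, fn), specificity = rate(tn, fp))
  list(ppv = rates[["ppv"]], npv = rates[["npv"]],
       sensitivity = rates[["sensitivity"]], specificity = rates[["specificity"]],
       undefined = is.nan(rates), confusion = as.list(counts))
}

lda_fold_ids <- function(n, k_folds) {
  if (is.null(k_folds) || k_folds >= n) return(seq_len(n))
  rep_len(seq_len(k_folds), n) # striped, deterministic
}

#' Morphology-based OA risk classification with leave-one-out CV
#'
#' Trains a linear discriminant (LDA) classifier of group membership from
#' (Mahalanobis-normalized) shape loadings and evaluates it by strict
#' leave-one-out cross-validation: each case is predicted by a model trained
#' on all remaining cases. All rates are computed from held-out predictions
#' only. The pointwise correlation is the point-biserial Pearson correlation
#' between the sign-stabilized held-out discriminant score and the binary
#' label.
#'
#' @param features numeric case-by-feature matrix.
#' @param labels two-level factor (or coercible) of group membership.
#' @param positive label treated as the positive (at-risk) class; defaults to
#'   the second factor level.
#' @param k_folds optional fold-count override; `NULL` (default) is strict
#'   leave-one-out.
#' @param strata optional per-case stratification labels (e.g. sex); when
#'   given, stratified copies of the report are attached under `per_stratum`.
#' @return a `classifier_report` with `ppv`, `npv`, `sensitivity`,
#'   `specificity`, `pointwise_correlation_r`, `p_value`, `confusion` counts,
#'   per-case held-out `scores` and `predicted`.
#' @export
lda_risk <- function(features, labels, positive = NULL, k_folds = NULL,
                     strata = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes required", call. = FALSE)
  if (min(table(labels)) < 2) stop("need at least 2 cases per class", call. = FALSE)
  positive <- positive %||% levels(labels)[2]
  if (!positive %in% levels(labels)) stop("unknown positive label", call. = FALSE)
  n <- nrow(features)
  folds <- lda_fold_ids(n, k_folds)
  scores <- numeric(n); predicted <- character(n)
  for (f in unique(folds)) {
    test <- which(folds == f); train <- which(folds != f)
    fit <- MASS::lda(features[train, , drop = FALSE], grouping = labels[train])
    tr_sc <- as.numeric(stats::predict(fit, features[train, , drop = FALSE])$x[, 1])
    flip <- if (mean(tr_sc[labels[train] == positive]) <
               mean(tr_sc[labels[train] != positive])) -1 else 1
    pr <- stats::predict(fit, features[test, , drop = FALSE])
    scores[test] <- flip * as.numeric(pr$x[, 1])
    predicted[test] <- as.character(pr$class)
  }
  truth_pos <- labels == positive
  pred_pos <- predicted == positive
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  cm <- confusion_metrics(tp, fp, tn, fn)
  ct <- suppressWarnings(stats::cor.test(scores, as.numeric(truth_pos)))
  report <- structure(c(cm, list(pointwise_correlation_r = unname(ct$estimate),
                                 p_value = ct$p.value, positive = positive,
                                 scores = scores, predicted = predicted,
                                 labels = labels)),
                      class = "classifier_report")
  if (!is.null(strata)) {
    strata <- factor(strata)
    report$per_stratum <- lapply(split(seq_len(n), strata), function(idx) {
      tpos <- truth_pos[idx]; ppos <- pred_pos[idx]
      cm_s <- confusion_metrics(sum(ppos & tpos), sum(ppos & !tpos),
                                sum(!ppos & !tpos), sum(!ppos & tpos))
      cm_s$pointwise_correlation_r <-
        suppressWarnings(stats::cor(scores[idx], as.numeric(tpos)))
      cm_s
    })
  }
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: PPV %.3f  NPV %.3f  sens %.3f  spec %.3f  r %.3f (p %.3g)\n",
              x$ppv, x$npv, x$sensitivity, x$specificity,
              x$pointwise_correlation_r, x$p_value))
  invisible(x)
}

#' 2-D embedding of a feature space
#'
#' Deterministic classical (metric) multidimensional scaling of the pairwise
#' Euclidean distances, for visual inspection of shape and wear spaces. The
#' embedding is visualization-only: no quantitative result of the package
#' depends on its geometry.
#'
#' @param features numeric case-by-feature matrix (>= 10 cases, finite).
#' @param seed accepted for interface stability; the embedding is
#'   deterministic and ignores it.
#' @return a case-by-2 coordinate matrix.
#' @export
embed_2d <- function(features, seed = 1) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 cases", call. = FALSE)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  xy <- stats::cmdscale(stats::dist(features), k = 2)
  colnames(xy) <- c("dim1", "dim2")
  xy
}
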