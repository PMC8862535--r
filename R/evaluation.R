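# Threshold-calibration and benchmarking metrics.

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties receiving half credit.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or 0/1) class labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    kc_abort("AUROC undefined: both classes must be present",
             "undefined_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step-wise)
#'
#' Computed as the step-function area \eqn{\sum_i (R_i - R_{i-1}) P_i} over
#' the distinct score thresholds in decreasing order (equal scores enter as
#' one block). No interpolation is applied. With uninformative constant
#' scores this equals the prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    kc_abort("AUPRC undefined: both classes must be present",
             "undefined_metric_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  npred <- tapply(y, grp, length)
  ctp <- cumsum(tp); cn <- cumsum(npred)
  recall <- ctp / np
  precision <- ctp / cn
  sum(diff(c(0, recall)) * precision)
}

#' Per-class sensitivity/specificity and overall accuracy
#'
#' @param pred,truth Character/factor vectors of predicted and true labels.
#' @return List with `per_class` (data.frame: class, sensitivity,
#'   specificity, n) and `accuracy`.
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  stopifnot(length(pred) == length(truth))
  classes <- sort(unique(c(pred, truth)))
  per <- do.call(rbind, lapply(classes, function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fn <- sum(pred != cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    tn <- sum(pred != cls & truth != cls)
    data.frame(class = cls,
               sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
               n = tp + fn)
  }))
  list(per_class = per, accuracy = mean(pred == truth))
}

#' Sweep the rejection threshold
#'
#' For every threshold in `grid`, applies [apply_threshold()] to the
#' first-tier probability matrix and records the unassigned fraction and —
#' when true labels are supplied — the accuracy among assigned cells. The
#' unassigned fraction is non-decreasing in the threshold by construction.
#'
#' @param probs Cells x classes probability matrix.
#' @param truth Optional true labels (same length as rows).
#' @param grid Thresholds to evaluate.
#' @return data.frame: threshold, unassigned_frac, accuracy_assigned.
#' @export
threshold_sweep <- function(probs, truth = NULL,
                            grid = seq(0, 1, by = 0.05)) {
  out <- lapply(grid, function(t) {
    lab <- apply_threshold(probs, t)
    assigned <- lab != "unassigned"
    data.frame(threshold = t,
               unassigned_frac = mean(!assigned),
               accuracy_assigned = if (!is.null(truth) && any(assigned))
                 mean(lab[assigned] == truth[assigned]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Probability-score distribution summaries by assigned class
#'
#' Summarizes the maximum first-tier score per cell, grouped by the assigned
#' tier-1 class: mean, SEM and quartiles. Mirrors the diagnostics used to
#' justify an operating threshold.
#'
#' @param ann A `kidclass_annotation` (from [predict.kidclass()]).
#' @param node Node whose probability columns are summarized (default the
#'   first tier).
#' @return data.frame keyed by assigned class.
#' @export
probability_summary <- function(ann, node = NULL) {
  pcols <- grep("^p_", colnames(ann), value = TRUE)
  if (!is.null(node)) pcols <- grep(paste0("^p_", node, "_"), pcols, value = TRUE)
  else {
    first <- sub("^p_([^_]+)_.*$", "\\1", pcols[1])
    pcols <- grep(paste0("^p_", first, "_"), pcols, value = TRUE)
  }
  mx <- do.call(pmax, c(ann[pcols], na.rm = TRUE))
  grp <- ann$tier1
  do.call(rbind, lapply(split(mx, grp), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
}
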