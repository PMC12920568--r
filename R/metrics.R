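# Binary-classification statistics reported by both pipeline stages.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,actual Logical (or 0/1) vectors.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  tibble::tibble(
    tp = sum(predicted & actual), tn = sum(!predicted & !actual),
    fp = sum(predicted & !actual), fn = sum(!predicted & actual)
  )
}

ratio_or_error <- function(num, den, what) {
  if (den == 0) stop("undefined ", what, ": zero denominator")
  num / den
}

#' Classification metrics from confusion counts
#'
#' Standard definitions: accuracy `(tp+tn)/N`, sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`,
#' F1 `2*Prec*Sn/(Prec+Sn)`, and the Matthews correlation coefficient. A
#' zero denominator is an error, except for MCC which follows the usual
#' convention of 0 with a warning.
#'
#' @param counts One-row tibble/list with `tp`, `tn`, `fp`, `fn`.
#' @return Numeric scalar.
#' @export
accuracy <- function(counts) {
  with(counts, ratio_or_error(tp + tn, tp + tn + fp + fn, "accuracy"))
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  with(counts, ratio_or_error(tp, tp + fn, "sensitivity"))
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  with(counts, ratio_or_error(tn, tn + fp, "specificity"))
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  with(counts, ratio_or_error(tp, tp + fp, "precision"))
}

#' @rdname accuracy
#' @export
f1_score <- function(counts) {
  pr <- precision(counts); sn <- sensitivity(counts)
  if (pr + sn == 0) stop("undefined F1: precision + sensitivity is zero")
  2 * pr * sn / (pr + sn)
}

#' @rdname accuracy
#' @export
mcc <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) {
    warning("MCC denominator is zero; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' Harmonic mean of sensitivity and specificity
#'
#' The balanced aggregate commonly reported by gene finders:
#' `2*Sn*Sp/(Sn+Sp)`; 0 with a warning when both are zero.
#'
#' @inheritParams accuracy
#' @export
harmonic_mean_sn_sp <- function(counts) {
  sn <- sensitivity(counts); sp <- specificity(counts)
  if (sn + sp == 0) {
    warning("Sn and Sp both zero; harmonic mean reported as 0")
    return(0)
  }
  2 * sn * sp / (sn + sp)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a random
#' positive outscores a random negative, with ties counting one half. Exact
#' under ties and identical to the explicit all-pairs comparison.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) class labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' All metrics as a one-row tibble
#'
#' @param counts Confusion counts.
#' @return Tibble with accuracy, sensitivity, specificity, harmonic mean,
#'   precision, F1 and MCC.
#' @export
classification_report <- function(counts) {
  tibble::tibble(
    accuracy = accuracy(counts),
    sensitivity = sensitivity(counts),
    specificity = specificity(counts),
    hm = harmonic_mean_sn_sp(counts),
    precision = precision(counts),
    f1 = f1_score(counts),
    mcc = mcc(counts)
  )
}
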