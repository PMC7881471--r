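metric_names <- c("ACC", "SEN", "SPE", "AUC", "Y", "F", "BAC")

# rank-statistic AUC (Mann-Whitney with midranks for ties)
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Computes accuracy (ACC), sensitivity (SEN, recall of the positive class),
#' specificity (SPE), rank-statistic AUC from decision scores, Youden's index
#' `Y = SEN + SPE - 1`, the F-score `F = 2 * precision * recall /
#' (precision + recall)` and balanced accuracy `BAC = (SEN + SPE) / 2`. The
#' high-self-esteem group (`"high"`) is the positive class by default.
#'
#' @param truth True labels (factor or character).
#' @param pred Predicted labels.
#' @param scores Optional decision scores, larger = more positive-like; AUC
#'   is `NA` without them. AUC is invariant under any strictly increasing
#'   transform of the scores.
#' @param positive Positive-class label.
#' @return One-row tibble with columns ACC, SEN, SPE, AUC, Y, F, BAC (all
#'   proportions in `[0, 1]`). If `truth` contains a single class, SEN or SPE
#'   (and the metrics derived from them) are `NaN` and a warning is raised.
#' @examples
#' compute_metrics(c("high", "low"), c("high", "low"), c(2, -1))
#' @export
compute_metrics <- function(truth, pred, scores = NULL, positive = "high") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  pos <- truth == positive
  tp <- sum(pos & pred == positive)
  fn <- sum(pos & pred != positive)
  tn <- sum(!pos & pred != positive)
  fp <- sum(!pos & pred == positive)
  if (all(pos) || all(!pos)) {
    warn("single-class truth: sensitivity or specificity is undefined (NaN)")
  }
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  fsc <- if ((2 * tp + fp + fn) == 0) NaN else 2 * tp / (2 * tp + fp + fn)
  auc <- if (is.null(scores)) NA_real_ else auc_rank(scores, pos)
  tibble::tibble(
    ACC = (tp + tn) / length(truth),
    SEN = sen, SPE = spe, AUC = auc,
    Y = sen + spe - 1, F = fsc, BAC = (sen + spe) / 2
  )
}
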