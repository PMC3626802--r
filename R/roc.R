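#' Area under the ROC curve, optionally direction-aware
#'
#' Plain mode: `labels` is a binary vector (0/1 or logical) and the AUC is
#' the trapezoidal area, equal to the Mann-Whitney U statistic divided by
#' n1 * n0 (ties get mean ranks).
#'
#' Sign-aware mode (`sign_aware = TRUE`): `labels` takes values in
#' \{-1, 0, +1\} giving the true direction of regulation (0 = not
#' differentially expressed) and `scores` are PPLR values. A gene is scored
#' by max(PPLR, 1 - PPLR) and counts as a true call only when it is truly
#' DE *and* the predicted direction (sign of PPLR - 0.5) matches the true
#' sign; a DE gene detected with the wrong direction is treated as a false
#' call, exactly like a non-DE gene with the same score.
#'
#' @param scores numeric vector (PPLR values in sign-aware mode).
#' @param labels binary labels, or signed labels in sign-aware mode.
#' @param sign_aware logical.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, sign_aware = FALSE) {
  if (length(scores) != length(labels))
    stop_usage("scores and labels must have equal length")
  if (sign_aware) {
    if (!all(labels %in% c(-1, 0, 1)))
      stop_usage("sign-aware labels must be in {-1, 0, +1}")
    pred_sign <- sign(scores - 0.5)
    truth <- labels != 0 & pred_sign == labels
    scores <- pmax(scores, 1 - scores)
    if (!any(labels != 0) || all(labels != 0))
      stop_usage("need at least one DE and one non-DE label")
    labels <- truth
  }
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop_usage("need at least one positive and one negative label")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
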