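#' Rank-based AUC for dichotomous outcome
#'
#' Area under the ROC curve of the rule "higher score implies poor
#' outcome", computed from ranks (the Mann-Whitney statistic), with tied
#' scores counted one half. The orientation is fixed: no folding of values
#' below 0.5, so an anti-predictive score yields an AUC below 0.5. The
#' orientation of gene scores is decided upstream by the sign of the fitted
#' training regression weight, never on test data.
#'
#' @param score numeric score vector.
#' @param label outcome per sample: `"good"`/`"poor"` character, factor, or
#'   0/1 with 1 = poor.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(score, label) {
  poor <- as_poor01(label)
  if (length(score) != length(poor)) stop("score/label length mismatch")
  n_p <- sum(poor == 1L)
  n_g <- sum(poor == 0L)
  if (n_p == 0 || n_g == 0)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[poor == 1L]) - n_p * (n_p + 1) / 2) / (n_p * n_g)
}

# normalize outcome labels to 0/1 with 1 = poor; rejects "excluded"
as_poor01 <- function(label) {
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(label))
  }
  label <- as.character(label)
  if (!all(label %in% c("good", "poor")))
    stop("labels must be 'good'/'poor' (excluded samples must be dropped first)")
  as.integer(label == "poor")
}

#' Synergy of a gene pair
#'
#' Ratio of the pair's (meta-gene) AUC to the better of the two individual
#' AUCs; values above 1 mean the combination beats both members.
#'
#' @param A_ij pair meta-gene AUC.
#' @param A_i,A_j individual gene AUCs.
#' @return synergy S = A_ij / max(A_i, A_j).
#' @export
synergy <- function(A_ij, A_i, A_j) {
  denom <- pmax(A_i, A_j)
  if (any(denom <= 0)) stop("max(A_i, A_j) must be positive")
  A_ij / denom
}
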