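#' Area under the ROC curve
#'
#' Nonparametric (Mann-Whitney) AUC: the probability that a randomly chosen
#' truth-positive case receives a higher score than a randomly chosen
#' truth-negative case, with ties counted half. Computed from mid-ranks.
#'
#' @param scores numeric scores, higher meaning more suspicious.
#' @param truth binary 0/1 vector of reference labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
roc_auc <- function(scores, truth) {
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]
  truth <- as.integer(truth[keep])
  if (!all(truth %in% c(0L, 1L))) {
    stop("truth must be coded 0/1", call. = FALSE)
  }
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs at least one positive and one negative case",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC point sequence
#'
#' Empirical ROC curve of a score against binary truth: one point per
#' distinct threshold (call positive when `score >= threshold`), beginning
#' at (0, 0) and ending at (1, 1); both coordinates are monotone
#' non-decreasing along the sequence.
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold` (descending; `Inf` for the
#'   all-negative corner), `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth) {
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]
  truth <- as.integer(truth[keep])
  if (!all(truth %in% c(0L, 1L))) {
    stop("truth must be coded 0/1", call. = FALSE)
  }
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative case",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # cumulative counts at each distinct score (last index of each tie group)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(t)[last]
  fp <- cumsum(1 - t)[last]
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}
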