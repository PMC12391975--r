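## Evaluation metrics for multilabel GO prediction.
##
## Fmax is protein-centric: at each threshold tau, precision is averaged
## over the m(tau) proteins that predict at least one term at tau, recall
## is averaged over all evaluable proteins, and Fmax is the maximum
## harmonic mean over a threshold grid.  AUC and AUPR are micro-averaged
## over all protein-term cells by default (macro-by-term optional).

as_matrix_pair <- function(labels, scores) {
  if (inherits(labels, "label_matrix")) labels <- labels$matrix
  labels <- as.matrix(labels)
  scores <- as.matrix(scores)
  if (!is.null(rownames(labels)) && !is.null(rownames(scores))) {
    if (!setequal(rownames(labels), rownames(scores))) {
      stop_graphgo("labels and scores cover different proteins")
    }
    scores <- scores[rownames(labels), , drop = FALSE]
    if (!is.null(colnames(labels)) && !is.null(colnames(scores))) {
      if (!setequal(colnames(labels), colnames(scores))) {
        stop_graphgo("labels and scores cover different terms")
      }
      scores <- scores[, colnames(labels), drop = FALSE]
    }
  }
  if (!all(dim(labels) == dim(scores))) {
    stop_graphgo("labels and scores have different shapes")
  }
  list(labels = labels, scores = scores)
}

#' Protein-centric Fmax
#'
#' For each threshold tau in the grid: per-protein precision is
#' TP / predicted-positive over the m(tau) proteins with at least one
#' score >= tau; per-protein recall is TP / true-positive, averaged over
#' all proteins with at least one true label (proteins without true
#' labels are excluded from recall averaging with a warning).  Fmax is
#' the maximum harmonic mean of the averaged precision and recall;
#' thresholds with m(tau) = 0 are skipped and ties resolve to the lowest
#' threshold.
#'
#' @param labels binary matrix (proteins x terms) or `label_matrix`.
#' @param scores numeric matrix in [0, 1], aligned with `labels` (by
#'   dimnames when present).
#' @param thresholds threshold grid, default `seq(0, 1, by = 0.01)`.
#' @return List with `fmax`, `threshold`, and the `precision` and
#'   `recall` attained there.
#' @export
fmax <- function(labels, scores, thresholds = seq(0, 1, by = 0.01)) {
  mp <- as_matrix_pair(labels, scores)
  L <- mp$labels; S <- mp$scores
  true_counts <- rowSums(L)
  if (any(true_counts == 0)) {
    warning(sprintf("%d protein(s) with zero true labels excluded from recall averaging",
                    sum(true_counts == 0)))
  }
  eval_rc <- true_counts > 0
  best <- list(fmax = 0, threshold = NA_real_, precision = NA_real_,
               recall = NA_real_)
  for (tau in thresholds) {
    pred <- S >= tau
    npred <- rowSums(pred)
    m_tau <- npred > 0
    if (!any(m_tau)) next
    tp <- rowSums(pred & (L == 1))
    pr <- mean((tp / npred)[m_tau])
    rc <- if (any(eval_rc)) mean((tp / true_counts)[eval_rc]) else 0
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f > best$fmax + 1e-15) {
      best <- list(fmax = f, threshold = tau, precision = pr, recall = rc)
    }
  }
  best
}

#' Micro- or macro-averaged ROC AUC
#'
#' Micro averaging pools all protein-term cells into one binary ranking
#' problem; the rank-based (Mann-Whitney) estimator with midranks for
#' ties equals the trapezoidal ROC area.  Macro averages the per-term
#' AUC over terms with both classes present.
#'
#' @inheritParams fmax
#' @param average "micro" (default) or "macro".
#' @return AUC in [0, 1].
#' @export
auc_score <- function(labels, scores, average = c("micro", "macro")) {
  average <- match.arg(average)
  mp <- as_matrix_pair(labels, scores)
  if (average == "micro") {
    return(auc_binary(as.numeric(mp$labels), as.numeric(mp$scores)))
  }
  per_term <- vapply(seq_len(ncol(mp$labels)), function(j) {
    y <- mp$labels[, j]
    if (all(y == 1) || all(y == 0)) NA_real_
    else auc_binary(y, mp$scores[, j])
  }, numeric(1))
  if (all(is.na(per_term))) stop_graphgo("no term with both classes present")
  mean(per_term, na.rm = TRUE)
}

auc_binary <- function(y, s) {
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop_graphgo("AUC needs both classes present")
  r <- rank(s)  # midranks handle ties as 0.5 credit
  (sum(r[y == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Micro- or macro-averaged area under the precision-recall curve
#'
#' Computed by the interpolated step method: thresholds descend through
#' the distinct scores and each recall increment is credited with the
#' precision attained at that threshold (tied scores move together).
#'
#' @inheritParams auc_score
#' @return AUPR in [0, 1].
#' @export
aupr_score <- function(labels, scores, average = c("micro", "macro")) {
  average <- match.arg(average)
  mp <- as_matrix_pair(labels, scores)
  if (average == "micro") {
    return(aupr_binary(as.numeric(mp$labels), as.numeric(mp$scores)))
  }
  per_term <- vapply(seq_len(ncol(mp$labels)), function(j) {
    y <- mp$labels[, j]
    if (all(y == 1) || all(y == 0)) NA_real_
    else aupr_binary(y, mp$scores[, j])
  }, numeric(1))
  if (all(is.na(per_term))) stop_graphgo("no term with both classes present")
  mean(per_term, na.rm = TRUE)
}

aupr_binary <- function(y, s) {
  P <- sum(y == 1)
  if (P == 0 || sum(y == 0) == 0) stop_graphgo("AUPR needs both classes present")
  ord <- order(-s)
  y <- y[ord]; s <- s[ord]
  grp_last <- which(diff(s) != 0)        # last index of each tie group
  cuts <- c(grp_last, length(s))
  tp <- cumsum(y)[cuts]
  pos_seen <- cuts
  prec <- tp / pos_seen
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Write a metrics report as a key-value text file
#' @param metrics named list of numbers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metrics)) {
    writeLines(sprintf("%s\t%.6f", k, as.numeric(metrics[[k]])), con)
  }
  invisible(path)
}
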