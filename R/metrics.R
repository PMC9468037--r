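#' Confusion matrix
#'
#' Counts of true class (rows) versus predicted class (columns) over the
#' union of observed levels (or supplied `levels`). Row sums equal the
#' per-class test counts.
#'
#' @param true,pred label vectors of equal length.
#' @param levels optional common level set.
#' @return integer matrix, rows = true, columns = predicted.
#' @export
confusion <- function(true, pred, levels = NULL) {
  stopifnot(length(true) == length(pred))
  if (is.null(levels)) levels <- sort(unique(c(as.character(true),
                                               as.character(pred))))
  t1 <- factor(as.character(true), levels = levels)
  t2 <- factor(as.character(pred), levels = levels)
  unclass(table(true = t1, pred = t2))
}

# per-class precision/recall/F1 from a confusion matrix; 0/0 counts as 0
.f1_per_class <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of the per-class F1 (harmonic mean of
#' precision and recall).
#'
#' @param cm confusion matrix from [confusion()], or `true` labels when
#'   `pred` is given.
#' @param pred optional predicted labels.
#' @return F1 in `[0, 1]`.
#' @export
f1_macro <- function(cm, pred = NULL) {
  if (!is.null(pred)) cm <- confusion(cm, pred)
  mean(.f1_per_class(cm))
}

#' Support-weighted F1 score
#'
#' Per-class F1 averaged with weights proportional to the true class
#' counts.
#'
#' @inheritParams f1_macro
#' @return F1 in `[0, 1]`.
#' @export
f1_weighted <- function(cm, pred = NULL) {
  if (!is.null(pred)) cm <- confusion(cm, pred)
  w <- rowSums(cm)
  sum(.f1_per_class(cm) * w) / sum(w)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two labelings over the same items:
#' `(po - pe) / (1 - pe)` with observed agreement `po` and the
#' marginal-product chance agreement `pe`. Symmetric in its arguments,
#' bounded in `[-1, 1]`, 0 at chance-level agreement; it is not
#' label-permutation invariant (labels must mean the same thing in both
#' inputs).
#'
#' @param a,b label vectors of equal length.
#' @return kappa.
#' @export
cohens_kappa <- function(a, b) {
  cm <- confusion(a, b)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Fowlkes-Mallows index
#'
#' Pair-counting agreement between two partitions: the geometric mean of
#' pairwise precision and recall, `TP / sqrt((TP + FP) (TP + FN))` over all
#' item pairs, where TP counts pairs co-clustered in both partitions. Being
#' pair-based it is invariant to label permutation and makes no assumption
#' about cluster structure.
#'
#' @param a,b partition label vectors of equal length (>= 2 items).
#' @return FMI in `[0, 1]`.
#' @export
fowlkes_mallows <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  cm <- confusion(a, b)
  tpfp <- sum(choose(colSums(cm), 2))
  tpfn <- sum(choose(rowSums(cm), 2))
  tp <- sum(choose(cm, 2))
  if (tpfp == 0 || tpfn == 0) return(0)
  tp / sqrt(tpfp * tpfn)
}

#' Majority-vote mapping from clusters to classes
#'
#' Assigns each cluster the most frequent reference class among its members
#' (ties to the alphabetically first class); used to compare an
#' unsupervised clustering against labeled classes.
#'
#' @param clusters cluster labels.
#' @param classes reference class labels, same length.
#' @return list `mapping` (named vector cluster -> class) and `mapped`
#'   (clusters translated to classes).
#' @export
map_clusters_to_classes <- function(clusters, classes) {
  stopifnot(length(clusters) == length(classes))
  cl <- as.character(clusters)
  mapping <- vapply(split(as.character(classes), cl), function(v) {
    tt <- sort(table(v), decreasing = TRUE)
    names(tt)[1]
  }, character(1))
  list(mapping = mapping, mapped = unname(mapping[cl]))
}

#' Distribution of prediction confidence per class
#'
#' For each predicted class, summary quantiles of the maximum-probability
#' confidence scores, plus the fraction of images with confidence above a
#' threshold.
#'
#' @param pred data frame `pred_class, confidence` (see [predict_class()]).
#' @param probs quantiles to report.
#' @param threshold confidence threshold for the exceedance fraction
#'   (default 0.6).
#' @return data frame, one row per class.
#' @export
confidence_distribution <- function(pred, probs = c(0.05, 0.25, 0.5, 0.75,
                                                    0.95),
                                    threshold = 0.6) {
  stopifnot(all(c("pred_class", "confidence") %in% names(pred)))
  out <- lapply(split(pred$confidence, pred$pred_class), function(v) {
    q <- quantile(v, probs)
    c(n = length(v), q, frac_above = mean(v > threshold))
  })
  res <- data.frame(pred_class = names(out), do.call(rbind, out),
                    check.names = FALSE, row.names = NULL)
  res
}
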