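## evaluate: strong/weak labeling from enrichment scores, ROC and
## precision-recall AUCs over predicted energies, correlations against
## measured affinities, and per-class density summaries.

#' Label sequences as strong or weak binders from enrichment scores
#'
#' Sequences with score above `hi` are strong binders (label 1); those below
#' `lo` are weak binders (label 0). If fewer than `min_weak` weak sequences
#' result, `lo` is raised through `fallback_los` in order until at least
#' `min_weak` weak sequences exist. Unlabeled sequences are dropped.
#'
#' @param scores `data.frame` with columns `sequence` and `score` (scores in
#'   `[0, 1]`; higher = stronger binder), or a named numeric vector.
#' @param hi Strong-binder threshold (default 0.9).
#' @param lo Initial weak-binder threshold (default 0.3).
#' @param fallback_los Thresholds tried in order when too few weak sequences
#'   (default `c(0.4, 0.5)`).
#' @param min_weak Minimum number of weak sequences (default 3).
#' @return `data.frame` with columns `sequence`, `score`, `label` plus
#'   attributes `hi` and `lo` (thresholds actually used).
#' @export
label_mword <- function(scores, hi = 0.9, lo = 0.3, fallback_los = c(0.4, 0.5),
                        min_weak = 3) {
  if (is.numeric(scores)) {
    scores <- data.frame(sequence = names(scores) %||% as.character(seq_along(scores)),
                         score = as.numeric(scores))
  }
  stopifnot(all(scores$score >= 0 & scores$score <= 1))
  los <- c(lo, fallback_los)
  used_lo <- NA_real_
  for (l in los) {
    if (sum(scores$score < l) >= min_weak) { used_lo <- l; break }
  }
  if (is.na(used_lo)) {
    stop("fewer than ", min_weak, " weak sequences even at lo = ",
         los[length(los)])
  }
  strong <- scores$score > hi
  weak <- scores$score < used_lo
  out <- scores[strong | weak, , drop = FALSE]
  out$label <- as.integer(strong[strong | weak])
  attr(out, "hi") <- hi
  attr(out, "lo") <- used_lo
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_labels <- function(energies, labels) {
  stopifnot(length(energies) == length(labels), all(labels %in% c(0L, 1L)))
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("both classes must be nonempty")
  }
}

#' ROC AUC of predicted energies against binary labels
#'
#' The positive class is "strong binder" and lower energy means a stronger
#' prediction, so energies are negated before applying the rank (Mann-
#' Whitney) statistic; ties receive midranks.
#'
#' @param energies Predicted energies (reduced units).
#' @param labels Binary labels, 1 = strong.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(energies, labels) {
  check_labels(energies, labels)
  score <- -energies
  r <- rank(score)  # midranks
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC of predicted energies against binary labels
#'
#' Builds the precision-recall curve over all score thresholds (tied scores
#' grouped) and integrates it by the trapezoidal rule; lower energy scores
#' as a stronger positive prediction.
#'
#' @inheritParams roc_auc
#' @return PR AUC in `[0, 1]`.
#' @export
pr_auc <- function(energies, labels) {
  check_labels(energies, labels)
  score <- -energies
  ord <- order(score, decreasing = TRUE)
  lab <- labels[ord]
  sc <- score[ord]
  ## threshold at the end of each tied-score group
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(lab == 1L)[keep]
  fp <- cumsum(lab == 0L)[keep]
  n_pos <- sum(labels == 1L)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  ## anchor at recall 0 with the first attainable precision
  recall <- c(0, recall)
  precision <- c(precision[1], precision)
  sum(diff(recall) * (precision[-1] + precision[-length(precision)]) / 2)
}

#' Class-balanced precision-recall AUC
#'
#' The majority class is subsampled to the minority-class size and the PR
#' AUC averaged over `n_rep` seeded subsamples. This interprets "balanced"
#' PR analysis as evaluation at a 1:1 class ratio.
#'
#' @inheritParams roc_auc
#' @param n_rep Number of subsampling repeats (default 20).
#' @param seed Integer seed.
#' @return Mean PR AUC over the subsamples.
#' @export
balanced_pr_auc <- function(energies, labels, n_rep = 20, seed = 1L) {
  check_labels(energies, labels)
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  n_min <- min(length(idx1), length(idx0))
  with_seed(seed, {
    mean(vapply(seq_len(n_rep), function(i) {
      take <- c(sample(idx1, n_min), sample(idx0, n_min))
      pr_auc(energies[take], labels[take])
    }, numeric(1)))
  })
}

#' Pearson and Spearman correlations of predictions against measurements
#'
#' @param predicted Predicted energies.
#' @param measured Measured free-energy differences.
#' @return List with elements `pearson` and `spearman` (`NA` with a warning
#'   when either vector has zero variance).
#' @export
correlations <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured), length(predicted) >= 3L)
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    warning("zero variance: correlations undefined", call. = FALSE)
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = stats::cor(predicted, measured),
       spearman = stats::cor(predicted, measured, method = "spearman"))
}

#' Per-class density summary of predicted energies
#'
#' Kernel density estimates and medians of predicted binding energies for
#' the strong and weak classes, plus the median gap
#' `median(weak) - median(strong)` (positive when strong binders are
#' predicted to bind more strongly, i.e. with lower energy).
#'
#' @inheritParams roc_auc
#' @param ... Passed to [stats::density()].
#' @return List with `strong_density`, `weak_density`, `median_strong`,
#'   `median_weak`, `median_gap`.
#' @export
density_separation <- function(energies, labels, ...) {
  check_labels(energies, labels)
  e1 <- energies[labels == 1L]
  e0 <- energies[labels == 0L]
  dens <- function(x) if (length(x) >= 2L && stats::sd(x) > 0) stats::density(x, ...) else NULL
  list(
    strong_density = dens(e1),
    weak_density = dens(e0),
    median_strong = stats::median(e1),
    median_weak = stats::median(e0),
    median_gap = stats::median(e0) - stats::median(e1)
  )
}

#' Write evaluation metrics as JSON and per-sequence predictions as TSV
#'
#' @param metrics Named list of scalar metrics.
#' @param predictions Optional `data.frame` of per-sequence predictions.
#' @param json_file,tsv_file Output paths (`NULL` to skip).
#' @export
write_metrics <- function(metrics, predictions = NULL, json_file = NULL,
                          tsv_file = NULL) {
  if (!is.null(json_file)) {
    jsonlite::write_json(metrics, json_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(predictions) && !is.null(tsv_file)) {
    utils::write.table(predictions, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
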