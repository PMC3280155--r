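#' Confusion counts
#'
#' @param TP,FP,FN,TN non-negative integers.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, FN, TN = 0) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Sensitivity, specificity and F-measure from confusion counts
#'
#' `Se = TP/(TP+FN)`; `Sp = TP/(TP+FP)`; `F = 2 Se Sp / (Se + Sp)`.
#' Note the definitional quirk preserved from the promoter-prediction
#' literature this package follows: *Sp* is TP-based (the proportion of
#' positive predictions that are correct, i.e. what is elsewhere called
#' precision), not the TN-based specificity. A metric with a zero
#' denominator is `NA`; `F` is 0 when `Se = Sp = 0`.
#'
#' @param c a [confusion_counts()].
#' @return Named list `Se`, `Sp`, `F`.
#' @examples
#' metrics_from_counts(confusion_counts(TP = 3, FP = 1, FN = 2))
#' @export
metrics_from_counts <- function(c) {
  Se <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  Sp <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  F <- if (is.na(Se) || is.na(Sp)) NA_real_
  else if (Se + Sp == 0) 0
  else 2 * Se * Sp / (Se + Sp)
  list(Se = Se, Sp = Sp, F = F)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midranks for tied scores, hence
#' invariant under strictly monotone score transforms: 0.5 is chance,
#' 1.0 perfect separation.
#'
#' @param scores real decision scores, higher = more promoter-like.
#' @param y logical labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_score <- function(scores, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)                      # midranks for ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, folds, seed = NULL) {
  y <- as.logical(y)
  if (min(sum(y), sum(!y)) < folds)
    stop("each class needs at least ", folds, " members for ", folds,
         "-fold CV")
  with_seed(seed, {
    id <- integer(length(y))
    for (cl in c(TRUE, FALSE)) {
      ix <- sample(which(y == cl))
      id[ix] <- rep_len(seq_len(folds), length(ix))
    }
    id
  })
}

#' Stratified cross-validated evaluation
#'
#' Stratified `folds`-fold CV; held-out decision scores and hard
#' predictions are pooled over folds (micro-averaged confusion counts)
#' before computing Se/Sp/F and the ROC score.
#'
#' @param fm a `feature_matrix`.
#' @param subset `selected_subset`, integer dims, or `NULL` for all
#'   dimensions.
#' @param classifier `"svm"` or `"knn"`.
#' @param folds number of folds.
#' @param seed RNG seed for fold assignment.
#' @return A `metrics_report`: `Se`, `Sp`, `F`, `ROC`, `counts`,
#'   `folds`, `seed`, `classifier`, `n_dims`.
#' @export
cross_validate <- function(fm, subset = NULL, classifier = c("svm", "knn"),
                           folds = 5, seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(fm, "feature_matrix"))
  dims <- if (is.null(subset)) seq_len(ncol(fm$X))
  else if (inherits(subset, "selected_subset")) subset$dims
  else as.integer(subset)
  fold_id <- stratified_folds(fm$y, folds, seed)
  scores <- numeric(length(fm$y))
  pred <- logical(length(fm$y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    cl <- train_classifier(fm$X[!test, dims, drop = FALSE], fm$y[!test],
                           classifier = classifier)
    sc <- predict(cl, fm$X[test, dims, drop = FALSE])
    scores[test] <- sc
    pred[test] <- sc > cl$threshold
  }
  cc <- confusion_counts(TP = sum(pred & fm$y), FP = sum(pred & !fm$y),
                         FN = sum(!pred & fm$y), TN = sum(!pred & !fm$y))
  m <- metrics_from_counts(cc)
  structure(c(m, list(ROC = roc_score(scores, fm$y), counts = cc,
                      folds = folds, seed = seed, classifier = classifier,
                      n_dims = length(dims), scores = scores)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d dims, %d-fold CV: Se %.3f  Sp %.3f  F %.3f  ROC %.3f\n",
              x$classifier, x$n_dims, x$folds, x$Se, x$Sp, x$F, x$ROC))
  invisible(x)
}

#' Write a metrics report as JSON and TSV
#'
#' @param report a `metrics_report`.
#' @param path output path without extension; writes `<path>.json` and
#'   `<path>.tsv`.
#' @export
write_metrics <- function(report, path) {
  flat <- list(classifier = report$classifier, n_dims = report$n_dims,
               folds = report$folds, Se = report$Se, Sp = report$Sp,
               F = report$F, ROC = report$ROC,
               TP = report$counts$TP, FP = report$counts$FP,
               FN = report$counts$FN, TN = report$counts$TN)
  jsonlite::write_json(flat, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(as.data.frame(flat), paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-feature share of a selected dimension subset
#'
#' For each structural feature, 100 times the number of subset dimensions
#' belonging to that feature over the subset size — the
#' feature-distribution statistic used to compare selection methods.
#' Ratios sum to 100.
#'
#' @param subset a `selected_subset` or integer dims.
#' @param fm the `feature_matrix` supplying the dimension index.
#' @return Named numeric vector of percentages (all features, zeros kept).
#' @export
feature_ratio <- function(subset, fm) {
  dims <- if (inherits(subset, "selected_subset")) subset$dims
  else as.integer(subset)
  if (!length(dims)) stop("empty subset")
  feats <- unique(fm$index$feature)
  f <- factor(fm$index$feature[dims], levels = feats)
  stats::setNames(100 * as.vector(table(f)) / length(dims), feats)
}

#' Pairwise Pearson correlation between structural features
#'
#' Correlates the per-feature position-wise mean profiles computed over a
#' sequence set (or already-built feature matrix): symmetric, unit
#' diagonal. High blocks flag redundant (e.g. energy-related) scales.
#'
#' @param x character vector of window sequences, or a `feature_matrix`.
#' @param scales scales (sequence input only).
#' @param ... passed to [average_profile()].
#' @return feature x feature correlation matrix.
#' @export
correlate_features <- function(x, scales = default_scales(), ...) {
  if (inherits(x, "feature_matrix")) {
    feats <- unique(x$index$feature)
    prof <- vapply(feats, function(f)
      colMeans(x$X[, dims_for_feature(x, f), drop = FALSE]),
      numeric(sum(x$index$feature == feats[1])))
  } else {
    prof <- vapply(scales, function(sc) average_profile(x, sc, ...),
                   numeric(length(window_positions())))
    colnames(prof) <- vapply(scales, `[[`, "", "name")
  }
  stats::cor(prof)
}

#' Match predicted TSS positions against annotations
#'
#' Greedy nearest-first one-to-one matching: prediction/annotation pairs
#' with `|distance| <= tol` (inclusive) are matched in order of increasing
#' distance, each side at most once. Matched predictions are TP, leftover
#' predictions FP, leftover annotations FN.
#'
#' @param predictions numeric vector of predicted genomic positions, or a
#'   `data.frame` with `chrom` and `pos` (matching then requires equal
#'   `chrom`).
#' @param annotated TSS table ([read_tss_bed()] layout) or numeric vector.
#' @param tol maximum distance in bp (default 500).
#' @return A [confusion_counts()] (TN is 0 by construction).
#' @export
match_tss <- function(predictions, annotated, tol = 500) {
  stopifnot(tol >= 0)
  pchrom <- if (is.data.frame(predictions)) predictions$chrom else
    rep("*", length(predictions))
  ppos <- if (is.data.frame(predictions)) predictions$pos else
    as.numeric(predictions)
  achrom <- if (is.data.frame(annotated)) annotated$chrom else
    rep("*", length(annotated))
  apos <- if (is.data.frame(annotated)) annotated$pos else
    as.numeric(annotated)
  pairs <- NULL
  for (i in seq_along(ppos)) {
    ok <- which(achrom == pchrom[i] & abs(apos - ppos[i]) <= tol)
    if (length(ok))
      pairs <- rbind(pairs, cbind(i, ok, abs(apos[ok] - ppos[i])))
  }
  tp <- 0L
  used_p <- logical(length(ppos)); used_a <- logical(length(apos))
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!used_p[i] && !used_a[j]) {
        used_p[i] <- TRUE; used_a[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  confusion_counts(TP = tp, FP = sum(!used_p), FN = sum(!used_a))
}
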