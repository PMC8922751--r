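# Validation harness: re-predict expression status from motif-count
# features with an rbf-kernel SVM and report accuracy, precision, recall
# and F1, so kernel-transformed motif sets can be compared against any
# externally supplied motif set under an identical split.

#' Motif-count feature matrix
#'
#' Cell (g, m) counts the q-passing scanner hits of motif m in gene g's
#' window. Genes without hits get zero rows; the result is invariant to the
#' order of the hits.
#'
#' @param hits data frame from [scan_motifs()] (already filtered at the
#'   scanner's q threshold).
#' @param genes character vector of all gene ids (rows; includes genes with
#'   no hits).
#' @param motifs character vector of motif names (columns; defaults to the
#'   motifs present in `hits`).
#' @return Integer matrix `length(genes)` x `length(motifs)`.
#' @export
feature_matrix <- function(hits, genes, motifs = NULL) {
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  X <- matrix(0L, nrow = length(genes), ncol = length(motifs),
              dimnames = list(genes, motifs))
  if (nrow(hits) > 0) {
    keep <- hits$gene %in% genes & hits$motif %in% motifs
    if (any(keep)) {
      tab <- table(factor(hits$gene[keep], levels = genes),
                   factor(hits$motif[keep], levels = motifs))
      X[] <- as.integer(tab)
    }
  }
  X
}

#' SVM re-prediction of expression status
#'
#' Fits an rbf-kernel SVM on the training rows of a motif-count feature
#' matrix and reports accuracy, precision, recall and F1 on the held-out
#' rows, with expressed as the positive class. Hyperparameter defaults:
#' `cost = 1` and `gamma = 1 / (n_features * var(X))` (overall feature
#' variance).
#'
#' @param X feature matrix from [feature_matrix()].
#' @param y labels aligned with the rows of `X` (expressed/low).
#' @param train_idx,test_idx row indices of the training and evaluation
#'   splits (reuse the classifier's test partition for comparability).
#' @param seed integer seed (SVM fitting is deterministic given the data;
#'   the seed fixes any tie-breaking).
#' @param cost SVM cost parameter.
#' @param gamma rbf bandwidth; `NULL` for the default above.
#' @return List: `accuracy`, `precision`, `recall`, `f1`, `confusion`, and
#'   `degenerate` (`TRUE` when the features are all-zero, in which case the
#'   metrics are still computed but flagged).
#' @export
svm_evaluate <- function(X, y, train_idx, test_idx, seed = 1L, cost = 1,
                         gamma = NULL) {
  y01 <- as_label01(y)
  if (length(unique(y01[train_idx])) < 2L) {
    stop("training split must contain both classes")
  }
  if (ncol(X) == 0L) {   # no motif ever hit: fall back to one zero feature
    X <- matrix(0L, nrow = nrow(X), ncol = 1L,
                dimnames = list(rownames(X), "none"))
  }
  degenerate <- all(X == 0)
  v <- stats::var(as.vector(X[train_idx, , drop = FALSE]))
  if (is.null(gamma)) {
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  yf <- factor(ifelse(y01 == 1L, "expressed", "low"),
               levels = c("expressed", "low"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- e1071::svm(x = X[train_idx, , drop = FALSE], y = yf[train_idx],
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
  truth <- yf[test_idx]
  tp <- sum(pred == "expressed" & truth == "expressed")
  fp <- sum(pred == "expressed" & truth == "low")
  fn <- sum(pred == "low" & truth == "expressed")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = mean(pred == truth), precision = precision,
       recall = recall, f1 = f1,
       confusion = table(predicted = pred, truth = truth),
       degenerate = degenerate)
}

#' Compare two motif sets through the identical SVM harness
#'
#' Feeds two feature matrices (e.g. kernel-transformed motifs vs an
#' externally supplied set) through [svm_evaluate()] with the same split
#' and seed, returning a paired metric table. The harness does not decide
#' which set "wins"; it only makes the four metrics comparable.
#'
#' @param feature_sets named list of feature matrices over the same genes.
#' @inheritParams svm_evaluate
#' @return Data frame: motif_set, accuracy, precision, recall, f1,
#'   degenerate.
#' @export
svm_compare <- function(feature_sets, y, train_idx, test_idx, seed = 1L,
                        cost = 1, gamma = NULL) {
  rows <- lapply(names(feature_sets), function(nm) {
    m <- svm_evaluate(feature_sets[[nm]], y, train_idx, test_idx,
                      seed = seed, cost = cost, gamma = gamma)
    data.frame(motif_set = nm, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               degenerate = m$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an SVM metrics table as TSV
#'
#' @param metrics data frame from [svm_compare()] (or a one-row equivalent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
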