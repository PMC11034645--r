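# Cross-validation split construction and evaluation metrics: ranking
# (AUROC / AUPR / Spearman), exposure-bias diagnostics over entity degrees,
# and literature-support analyses of ranked predictions.

#' Entry-wise stratified five-fold split of a binary association matrix
#'
#' Entries are partitioned into `k` folds with the positive:negative ratio
#' of each fold within one entry of exact stratification. For each fold,
#' 10% of the non-test entries are sampled (stratified) as validation and
#' the rest are training. Deterministic per seed.
#'
#' @param tda binary matrix (e.g. the target-disease association grid).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param val_fraction validation fraction of non-test entries.
#' @return a `split_plan`: per fold, linear-index vectors `test`,
#'   `validation`, `train` partitioning all entries.
#' @export
entrywise_folds <- function(tda, k = 5, seed = 1, val_fraction = 0.1) {
  set.seed(seed)
  pos <- which(tda == 1)
  neg <- which(tda != 1)
  if (length(pos) < k) {
    warning(sprintf("fewer positives (%d) than folds (%d); stratification degrades",
                    length(pos), k))
  }
  fold_of <- integer(length(tda))
  if (length(pos)) fold_of[sample(pos)] <- rep_len(seq_len(k), length(pos))
  if (length(neg)) fold_of[sample(neg)] <- rep_len(seq_len(k), length(neg))
  build_split_plan(tda, fold_of, k, seed, val_fraction, scheme = "entry")
}

build_split_plan <- function(tda, fold_of, k, seed, val_fraction, scheme,
                             cluster_of = NULL) {
  folds <- vector("list", k)
  labels <- as.integer(tda == 1)
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    rest <- which(fold_of != f)
    val <- integer(0)
    for (cls in unique(labels[rest])) {
      cand <- rest[labels[rest] == cls]
      n_take <- round(val_fraction * length(cand))
      if (n_take > 0) val <- c(val, sample(cand, n_take))
    }
    val <- sort(val)
    folds[[f]] <- list(test = sort(test), validation = val,
                       train = sort(setdiff(rest, val)))
  }
  structure(list(scheme = scheme, k = k, seed = seed, dim = dim(tda),
                 folds = folds, cluster_of = cluster_of),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s-wise, %d folds over %dx%d entries (seed %d)\n",
              x$scheme, x$k, x$dim[1], x$dim[2], x$seed))
  for (f in seq_len(x$k)) {
    cat(sprintf("  fold %d: %d test / %d val / %d train\n", f,
                length(x$folds[[f]]$test), length(x$folds[[f]]$validation),
                length(x$folds[[f]]$train)))
  }
  invisible(x)
}

# pairwise Jaccard similarity between binary columns; two all-zero columns
# count as identical (similarity 1)
jaccard_columns <- function(tda) {
  X <- (tda == 1) * 1
  inter <- crossprod(X)
  cs <- colSums(X)
  uni <- outer(cs, cs, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 1)
  J
}

#' Cluster-wise five-fold split of a binary association matrix
#'
#' Columns (disease association profiles) are clustered by average-linkage
#' agglomerative clustering on the distance 1 - Jaccard; whole clusters are
#' assigned to folds, largest cluster first into the currently smallest
#' fold, so that similar columns never straddle the train/test boundary. A
#' cluster holding more than `1/k` of all columns is split at a lower
#' dendrogram level (with a warning). Validation entries are then sampled
#' exactly as in [entrywise_folds()].
#'
#' @inheritParams entrywise_folds
#' @return a `split_plan` whose test masks are unions of whole columns.
#' @export
clusterwise_folds <- function(tda, k = 5, seed = 1, val_fraction = 0.1) {
  stopifnot(all(tda %in% c(0, 1)))
  set.seed(seed)
  n_col <- ncol(tda)
  D <- stats::as.dist(1 - jaccard_columns(tda))
  hc <- stats::hclust(D, method = "average")
  max_size <- ceiling(n_col / k)
  n_clust <- k
  repeat {
    cl <- stats::cutree(hc, k = n_clust)
    sizes <- table(cl)
    if (max(sizes) <= max_size || n_clust >= n_col) break
    n_clust <- n_clust + 1L
  }
  if (n_clust > k) {
    warning(sprintf("cluster exceeding 1/%d of columns split at a lower dendrogram level (%d clusters)",
                    k, n_clust))
  }
  # largest cluster first into the fold currently holding fewest columns
  ord <- order(-as.integer(table(cl)[as.character(seq_len(max(cl)))]))
  fold_cols <- integer(n_col)
  load <- integer(k)
  for (cid in ord) {
    f <- which.min(load)
    cols <- which(cl == cid)
    fold_cols[cols] <- f
    load[f] <- load[f] + length(cols)
  }
  fold_of <- matrix(rep(fold_cols, each = nrow(tda)), nrow(tda), n_col)
  build_split_plan(tda, as.integer(fold_of), k, seed, val_fraction,
                   scheme = "cluster", cluster_of = cl)
}

#' Area under the ROC curve
#'
#' Mann-Whitney probability of ranking a random positive above a random
#' negative, with the tie correction (ties count 1/2).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels == 1)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop_probkg("AUROC undefined for single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area: scores are swept in descending order (ties
#' grouped at one threshold) and the area accumulates
#' `(recall_t - recall_{t-1}) * precision_t`.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels == 1)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop_probkg("AUPR undefined for single-class labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' Returns `NA` (flagged via a "zero-variance" attribute-free convention)
#' when either input has zero rank variance.
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Observed degree counts of a binary association matrix
#'
#' `k_t` counts the diseases associated with each target (row sums); `k_d`
#' counts the targets associated with each disease (column sums).
#'
#' @param tda binary matrix (targets x diseases).
#' @return list with `k_t` and `k_d`.
#' @export
degree_counts <- function(tda) {
  list(k_t = rowSums(tda == 1), k_d = colSums(tda == 1))
}

#' Performance on low-information subsets (exposure-bias diagnostic)
#'
#' AUPR restricted to entries whose target degree `k_t` (resp. disease
#' degree `k_d`) is strictly below each threshold. Empty or single-class
#' subsets are reported as `NA` (undefined), not zero.
#'
#' @param pred score matrix.
#' @param tda binary label matrix of the same shape.
#' @param kt_thresholds,kd_thresholds degree thresholds.
#' @return list of two named numeric vectors, `by_kt` and `by_kd`.
#' @export
subset_performance <- function(pred, tda, kt_thresholds = c(100, 300, 500),
                               kd_thresholds = c(10, 30, 50)) {
  deg <- degree_counts(tda)
  one <- function(keep_rows = NULL, keep_cols = NULL) {
    keep <- matrix(TRUE, nrow(tda), ncol(tda))
    if (!is.null(keep_rows)) keep[!keep_rows, ] <- FALSE
    if (!is.null(keep_cols)) keep[, !keep_cols] <- FALSE
    if (!any(keep) || length(unique(tda[keep])) < 2) return(NA_real_)
    aupr(pred[keep], tda[keep])
  }
  by_kt <- vapply(kt_thresholds, function(th) one(keep_rows = deg$k_t < th), 0)
  by_kd <- vapply(kd_thresholds, function(th) one(keep_cols = deg$k_d < th), 0)
  list(by_kt = stats::setNames(by_kt, paste0("kt<", kt_thresholds)),
       by_kd = stats::setNames(by_kd, paste0("kd<", kd_thresholds)))
}

#' Correlation of target-wise maximum scores with target degree
#'
#' Spearman correlation between each target's maximum prediction score and
#' its observed degree `k_t`; high values indicate exposure bias (top
#' predictions track the amount of observed information).
#'
#' @param pred score matrix (targets x diseases).
#' @param k_t per-target observed degrees.
#' @return Spearman rho (or `NA` when undefined).
#' @export
maxscore_degree_correlation <- function(pred, k_t) {
  spearman(apply(pred, 1, max), k_t)
}

#' Row-wise significant entries
#'
#' Per row, flags the entries whose score strictly exceeds the row mean plus
#' two row standard deviations (population standard deviation).
#'
#' @param pred score matrix.
#' @return logical matrix of the same shape.
#' @export
significant_entries <- function(pred) {
  mu <- rowMeans(pred)
  sg <- sqrt(rowMeans((pred - mu)^2))
  pred > mu + 2 * sg
}

#' Ranked novel predictions
#'
#' Significant entries that are unobserved in the input associations,
#' sorted by descending score with a deterministic (row, column) tie-break.
#'
#' @param significant logical matrix (e.g. from [significant_entries()]).
#' @param observed logical/binary matrix of observed associations.
#' @param scores score matrix.
#' @return data.frame with columns `row`, `col`, `score`.
#' @export
novel_predictions <- function(significant, observed, scores) {
  keep <- significant & !(observed == 1)
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2], score = scores[keep])
  out[order(-out$score, out$row, out$col), , drop = FALSE]
}

#' Literature support among top predictions
#'
#' Among the `top_n` ranked predictions, counts those whose co-occurrence
#' value is strictly greater than each threshold.
#'
#' @param ranked data.frame from [novel_predictions()] (or any ranked
#'   `row`/`col` list).
#' @param C_tda co-occurrence count matrix for the target-disease relation.
#' @param top_n number of top predictions considered.
#' @param thresholds count thresholds.
#' @return named integer vector of counts.
#' @export
literature_support_counts <- function(ranked, C_tda, top_n = 200,
                                      thresholds = c(0, 5, 25)) {
  top <- utils::head(ranked, top_n)
  cv <- C_tda[cbind(top$row, top$col)]
  stats::setNames(vapply(thresholds, function(th) sum(cv > th), 0L),
                  paste0("C>", thresholds))
}

#' Correlation of top-k prediction scores with co-occurrence counts
#'
#' For each `k`, the Spearman correlation between the top-`k` prediction
#' scores and their co-occurrence values; `NA` when undefined (e.g. all
#' counts identical).
#'
#' @inheritParams literature_support_counts
#' @param ks top-list sizes.
#' @return named numeric vector of correlations.
#' @export
topk_cr_correlation <- function(ranked, C_tda,
                                ks = c(200, 500, 1000, 1500, 2000, 2500, 3000)) {
  out <- vapply(ks, function(k) {
    top <- utils::head(ranked, k)
    spearman(top$score, C_tda[cbind(top$row, top$col)])
  }, 0)
  stats::setNames(out, paste0("top", ks))
}

#' Evaluation report
#'
#' Bundles overall ranking metrics with the exposure-bias and
#' literature-support diagnostics.
#'
#' @param pred score matrix (targets x diseases).
#' @param tda binary observed association matrix.
#' @param C_tda optional co-occurrence matrix for literature diagnostics.
#' @param test_idx optional linear indices restricting AUROC/AUPR to held
#'   out entries (labels from `labels` if given, else from `tda`).
#' @param labels optional label matrix overriding `tda` for scoring (e.g.
#'   ground truth including held-out positives).
#' @return an `eval_report` list.
#' @export
eval_report <- function(pred, tda, C_tda = NULL, test_idx = NULL, labels = NULL) {
  lab <- labels %||% tda
  sc <- if (is.null(test_idx)) as.numeric(pred) else pred[test_idx]
  lb <- if (is.null(test_idx)) as.numeric(lab) else lab[test_idx]
  rep_ <- list(
    auroc = auroc(sc, lb),
    aupr = aupr(sc, lb),
    subsets = subset_performance(pred, tda),
    max_score_kt_spearman = maxscore_degree_correlation(pred, degree_counts(tda)$k_t)
  )
  if (!is.null(C_tda)) {
    ranked <- novel_predictions(significant_entries(pred), tda, pred)
    rep_$literature_counts <- literature_support_counts(ranked, C_tda)
    rep_$topk_spearman <- topk_cr_correlation(ranked, C_tda)
  }
  structure(rep_, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUROC %.4f, AUPR %.4f\n", x$auroc, x$aupr))
  cat("  AUPR by k_t:", paste(sprintf("%s=%.3f", names(x$subsets$by_kt), x$subsets$by_kt),
                              collapse = " "), "\n")
  cat("  AUPR by k_d:", paste(sprintf("%s=%.3f", names(x$subsets$by_kd), x$subsets$by_kd),
                              collapse = " "), "\n")
  cat(sprintf("  Spearman(max score, k_t) = %.4f\n", x$max_score_kt_spearman))
  if (!is.null(x$literature_counts)) {
    cat("  top-200 literature support:",
        paste(sprintf("%s:%d", names(x$literature_counts), x$literature_counts),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Serialize / load a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path JSON file path.
#' @return `path` (write) or the `split_plan` (read).
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$folds <- lapply(seq_len(nrow_or_len(x$folds)), function(i) {
    f <- if (is.data.frame(x$folds)) lapply(x$folds, `[[`, i) else x$folds[[i]]
    lapply(f, as.integer)
  })
  structure(x, class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
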