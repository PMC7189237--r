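#' Confusion matrix for the photosynthetic (positive) class
#'
#' @param tp,tn,fp,fn non-negative counts; the positive class is "T"
#'   (photosynthetic).
#' @return `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from labeled predictions
#'
#' Predictions of `NOT_ASSIGNABLE` on a labeled query are counted as wrong
#' (a missed positive or a false alarm on a negative is what an unusable
#' prediction costs in practice).
#'
#' @param truth character vector of "T"/"F".
#' @param pred character vector of "T"/"F"/"NOT_ASSIGNABLE".
#' @return `confusion_matrix`.
#' @export
confusion_from_predictions <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  wrong <- pred == "NOT_ASSIGNABLE"
  eff <- ifelse(wrong, ifelse(truth == "T", "F", "T"), pred)
  confusion_matrix(tp = sum(truth == "T" & eff == "T"),
                   tn = sum(truth == "F" & eff == "F"),
                   fp = sum(truth == "F" & eff == "T"),
                   fn = sum(truth == "T" & eff == "F"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion (positive = T): TP", x$tp, "TN", x$tn, "FP", x$fp, "FN", x$fn, "\n")
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall, F1 of the minor (positive) class and
#' Matthews correlation coefficient.  Any metric whose denominator is zero
#' is 0 by convention (relevant only for degenerate folds).
#'
#' @param cm `confusion_matrix` (or list with tp/tn/fp/fn).
#' @return named numeric vector: accuracy, precision, recall, f1_minor, mcc.
#' @export
compute_metrics <- function(cm) {
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  div <- function(num, den) if (den == 0) 0 else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(accuracy = div(tp + tn, tp + tn + fp + fn),
    precision = precision,
    recall = recall,
    f1_minor = if (precision + recall == 0) 0
               else 2 * precision * recall / (precision + recall),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

.entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gain ratio of a nominal feature against nominal labels
#'
#' Information gain `H(Y) - H(Y|A)` normalised by the feature's own entropy
#' `H(A)` (log base 2).  A constant feature has gain ratio 0 by convention.
#'
#' @param feature nominal vector.
#' @param labels nominal vector of the same length.
#' @return gain ratio in `[0, 1]`.
#' @export
gain_ratio <- function(feature, labels) {
  if (length(feature) != length(labels)) stop("feature/label length mismatch")
  ha <- .entropy(feature)
  if (ha == 0) return(0)
  hy <- .entropy(labels)
  hy_a <- sum(vapply(split(labels, feature), function(part) {
    length(part) / length(labels) * .entropy(part)
  }, numeric(1)))
  (hy - hy_a) / ha
}

#' Select the k features with highest gain ratio
#'
#' Deterministic ranking: descending gain ratio, ties broken by column name.
#'
#' @param x matrix of nominal-coded features (columns named).
#' @param labels class labels.
#' @param k number of columns to keep (1 <= k <= ncol).
#' @return list: `columns` (selected names in rank order), `gain_ratio`
#'   (named full ranking), `composition` (selected-count per threshold tag
#'   when column names are "tag:family").
#' @export
select_top_features <- function(x, labels, k) {
  if (k <= 0) stop("k must be positive")
  if (k > ncol(x)) stop("k exceeds the number of features")
  gr <- vapply(colnames(x), function(nm) gain_ratio(x[, nm], labels), numeric(1))
  o <- order(-gr, names(gr))
  sel <- names(gr)[o][seq_len(k)]
  tags <- sub(":.*$", "", sel)
  list(columns = sel, gain_ratio = gr[o],
       composition = table(factor(tags, levels = unique(sub(":.*$", "", colnames(x))))))
}

#' Fit a PCA reduction retaining a target variance fraction
#'
#' Levels are treated as numeric; components are kept up to the smallest
#' count reaching `variance_retained` of the total variance.  The fitted
#' transform is reusable on held-out data.
#'
#' @param x numeric matrix (rows = instances).
#' @param variance_retained fraction in (0, 1] (default 0.95).
#' @return `pca_transform`: list with `rotation`, `center`, `k`, `scores`.
#' @export
pca_reduce <- function(x, variance_retained = 0.95) {
  stopifnot(variance_retained > 0, variance_retained <= 1)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty input to PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- cumsum(v) / sum(v)
  k <- which(frac >= variance_retained - 1e-12)[1L]
  if (is.na(k)) k <- length(v)
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, k = k,
                 scores = pc$x[, seq_len(k), drop = FALSE]),
            class = "pca_transform")
}

#' Apply a fitted PCA transform to new data
#' @param object `pca_transform`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return score matrix with `k` columns.
#' @export
predict.pca_transform <- function(object, newdata, ...) {
  scale(newdata, center = object$center, scale = FALSE) %*% object$rotation
}

#' SMOTE oversampling of the minority class
#'
#' For each synthetic row a minority instance is paired with one of its
#' `k_neighbors` nearest minority neighbors (Euclidean distance on the
#' level-coded features) and a point is drawn uniformly on the connecting
#' segment.  `rate = 100` creates one synthetic row per minority row.
#'
#' @param x numeric matrix of minority-class rows (> `k_neighbors` rows).
#' @param k_neighbors neighborhood size (default 5).
#' @param rate oversampling percentage (default 100).
#' @param seed integer seed.
#' @return matrix of synthetic rows (same columns).
#' @export
smote_oversample <- function(x, k_neighbors = 5L, rate = 100, seed = 1L) {
  n <- nrow(x)
  if (n <= k_neighbors)
    stop("need more than k_neighbors = ", k_neighbors, " minority rows")
  n_syn <- round(n * rate / 100)
  if (n_syn == 0L) return(x[0L, , drop = FALSE])
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k_neighbors)]))
  .with_seed(seed, {
    base_idx <- rep_len(seq_len(n), n_syn)
    nb_idx <- nn[cbind(base_idx, sample.int(k_neighbors, n_syn, replace = TRUE))]
    gap <- stats::runif(n_syn)
    x[base_idx, , drop = FALSE] +
      gap * (x[nb_idx, , drop = FALSE] - x[base_idx, , drop = FALSE])
  })
}

#' Balanced instance reweighting
#'
#' Each class's weights sum to the same value while the total weight stays
#' equal to the instance count (so a 257/772 split gives per-instance
#' weights of about 2.002 and 0.666).
#'
#' @param labels class labels (two classes present).
#' @return numeric weight per instance.
#' @export
reweight_balanced <- function(labels) {
  tab <- table(labels)
  tab <- tab[tab > 0]
  if (length(tab) < 2L) stop("reweighting needs both classes present")
  n <- length(labels)
  w_class <- n / (length(tab) * as.numeric(tab))
  names(w_class) <- names(tab)
  unname(w_class[as.character(labels)])
}
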