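#' Fit a photosynthetic-protein classifier on a discretized profile
#'
#' The central model of the package: a classifier over genome-neighborhood
#' conservation levels separating photosynthetic ("T") from
#' non-photosynthetic ("F") proteins.  Random forest is the primary and
#' default algorithm; a linear-kernel SVM and a naive Bayes network stand in
#' for the SMO and Bayesian-network alternatives.
#'
#' @param x feature matrix of conservation levels (rows = instances), or a
#'   `discretized_profile`.
#' @param labels "T"/"F" labels (taken from the profile when `x` is one).
#' @param classifier `"rf"` (default), `"svm"` or `"nb"`.
#' @param weights optional per-instance case weights (used by `"rf"` via
#'   sampling and `"svm"`/`"nb"` where supported; see Details).
#' @param ntree,maxnodes random-forest size controls (`maxnodes = NA` grows
#'   unrestricted trees).
#' @param cost SVM cost parameter.
#' @param seed integer seed controlling any training randomness.
#' @return object of class `photomod` with `predict`, `print` and `summary`
#'   methods.
#' @details Case weights: random forest uses `classwt` derived from the
#'   aggregated class weights; the naive Bayes path ignores weights (its
#'   class priors are adjusted instead).
#' @export
photomod <- function(x, labels = NULL, classifier = c("rf", "svm", "nb"),
                     weights = NULL, ntree = 500L, maxnodes = NA,
                     cost = 1, seed = 1L) {
  classifier <- match.arg(classifier)
  if (inherits(x, "discretized_profile")) {
    labels <- x$labels
    x <- x$x
    keep <- labels %in% c("T", "F")
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (is.null(labels)) stop("labels required")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(labels, levels = c("F", "T"))
  if (any(is.na(y))) stop("labels must be T or F")
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  model <- switch(classifier,
    rf = .with_seed(seed, {
      classwt <- NULL
      if (!is.null(weights)) {
        agg <- tapply(weights, y, sum)
        classwt <- agg / sum(agg)
      }
      args <- list(x = as.data.frame(xm), y = y, ntree = as.integer(ntree),
                   classwt = classwt)
      if (!is.na(maxnodes))
        args$maxnodes <- as.integer(min(maxnodes, nrow(xm)))
      do.call(randomForest::randomForest, args)
    }),
    svm = .with_seed(seed, e1071::svm(x = xm, y = y, kernel = "linear",
                                      cost = cost, scale = FALSE,
                                      class.weights = if (is.null(weights)) NULL else {
                                        agg <- tapply(weights, y, mean)
                                        agg / min(agg)
                                      })),
    nb = {
      df <- as.data.frame(lapply(as.data.frame(xm),
                                 function(v) factor(v, levels = sort(unique(as.vector(xm))))))
      e1071::naiveBayes(x = df, y = y, laplace = 1)
    })
  structure(list(classifier = classifier, model = model,
                 feature_names = colnames(xm),
                 nb_levels = if (classifier == "nb") sort(unique(as.vector(xm))) else NULL,
                 hyper = list(ntree = ntree, maxnodes = maxnodes, cost = cost),
                 seed = seed,
                 n_train = nrow(xm), class_counts = table(y)),
            class = "photomod")
}

#' Predict photosynthetic class with a fitted model
#' @param object `photomod`.
#' @param newdata matrix (or `discretized_profile`) with the training
#'   feature columns; missing columns are zero-filled, extra columns dropped.
#' @param ... unused.
#' @return factor of "F"/"T" predictions.
#' @export
predict.photomod <- function(object, newdata, ...) {
  if (inherits(newdata, "discretized_profile")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) {
    fill <- matrix(0, nrow(newdata), length(miss),
                   dimnames = list(rownames(newdata), miss))
    newdata <- cbind(newdata, fill)
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  out <- switch(object$classifier,
    rf = stats::predict(object$model, as.data.frame(newdata)),
    svm = stats::predict(object$model, newdata),
    nb = {
      df <- as.data.frame(lapply(as.data.frame(newdata),
                                 function(v) factor(v, levels = object$nb_levels)))
      stats::predict(object$model, df)
    })
  factor(as.character(out), levels = c("F", "T"))
}

#' @export
print.photomod <- function(x, ...) {
  cat("photomod classifier (", x$classifier, "), trained on ", x$n_train,
      " instances (F=", x$class_counts[["F"]], ", T=", x$class_counts[["T"]],
      "), ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' @export
summary.photomod <- function(object, ...) {
  print(object)
  if (object$classifier == "rf") {
    cat("OOB error:", round(object$model$err.rate[object$model$ntree, "OOB"], 4), "\n")
  }
  invisible(object)
}

# stratified fold assignment; error if a fold would lack a class
.stratified_folds <- function(labels, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# per-fold preprocessing + fit; returns predictions on test rows
.fit_predict <- function(xtr, ytr, xte, classifier, hyper, select_k, pca,
                         balance, cutpoints, seed) {
  # discretize with cutpoints fitted on the training rows only
  lev <- function(v, q) {
    out <- integer(length(v))
    out[v > 0 & v <= q[1L]] <- 1L
    out[v > q[1L] & v <= q[2L]] <- 2L
    out[v > q[2L]] <- 3L
    out
  }
  dtr <- apply(xtr, 2L, lev, q = cutpoints)
  dte <- apply(xte, 2L, lev, q = cutpoints)
  dim(dtr) <- dim(xtr); dimnames(dtr) <- dimnames(xtr)
  dim(dte) <- dim(xte); dimnames(dte) <- dimnames(xte)
  if (!is.null(select_k) && select_k < ncol(dtr)) {
    sel <- select_top_features(dtr, ytr, select_k)$columns
    dtr <- dtr[, sel, drop = FALSE]
    dte <- dte[, sel, drop = FALSE]
  }
  weights <- NULL
  if (balance == "smote") {
    minority <- names(which.min(table(ytr)))
    xmin <- dtr[ytr == minority, , drop = FALSE]
    if (nrow(xmin) > 5L) {
      syn <- smote_oversample(xmin, seed = seed)
      dtr <- rbind(dtr, syn)
      ytr <- c(as.character(ytr), rep(minority, nrow(syn)))
    } else ytr <- as.character(ytr)
  } else if (balance == "reweight") {
    weights <- reweight_balanced(ytr)
    ytr <- as.character(ytr)
  } else ytr <- as.character(ytr)
  if (!is.null(pca)) {
    tr <- pca_reduce(dtr, pca)
    dtr <- tr$scores
    dte <- predict(tr, dte)
    colnames(dtr) <- colnames(dte) <- paste0("PC", seq_len(ncol(dtr)))
  }
  fit <- photomod(dtr, ytr, classifier = classifier, weights = weights,
                  ntree = hyper$ntree %||% 500L,
                  maxnodes = hyper$maxnodes %||% NA,
                  cost = hyper$cost %||% 1, seed = seed)
  as.character(predict(fit, dte))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_grid <- function(classifier) {
  switch(classifier,
         rf = list(list(ntree = 100L, maxnodes = NA), list(ntree = 500L, maxnodes = NA),
                   list(ntree = 100L, maxnodes = 32L), list(ntree = 500L, maxnodes = 32L)),
         svm = list(list(cost = 0.1), list(cost = 1), list(cost = 10)),
         nb = list(list()))
}

#' Nested cross-validation of the neighborhood-profile classifier
#'
#' Stratified outer folds estimate performance; inner folds, built only from
#' each outer training set, pick the hyperparameter combination with the
#' best F1 of the minor class.  Quartile cutpoints, gain-ratio feature
#' selection, PCA and class balancing are all fitted inside the outer
#' training set, so no information from a held-out fold reaches the model.
#'
#' @param profile `neighborhood_profile` (numeric Phylo scores) with T/F
#'   labels.
#' @param classifier `"rf"`, `"svm"` or `"nb"`.
#' @param outer,inner fold counts (defaults 10 and 2).
#' @param grid list of hyperparameter lists to tune over (default per
#'   classifier).
#' @param select_k optional gain-ratio feature count.
#' @param pca optional PCA variance fraction.
#' @param balance `"none"`, `"smote"` or `"reweight"`.
#' @param seed integer seed.
#' @return `photomod_cv`: per-fold metric matrix, mean/sd per metric and the
#'   pooled confusion matrix.
#' @export
nested_cv <- function(profile, classifier = "rf", outer = 10L, inner = 2L,
                      grid = NULL, select_k = NULL, pca = NULL,
                      balance = c("none", "smote", "reweight"), seed = 1L) {
  balance <- match.arg(balance)
  if (is.null(grid)) grid <- .default_grid(classifier)
  keep <- profile$labels %in% c("T", "F")
  x <- profile$x[keep, , drop = FALSE]
  y <- profile$labels[keep]
  folds <- .stratified_folds(y, outer, seed)
  fold_metrics <- list()
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (f in seq_len(outer)) {
    tr <- folds != f; te <- folds == f
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 1L)
      stop("outer fold ", f, " lacks a class; try a different seed")
    cutpoints <- tryCatch(
      .fit_cutpoints_matrix(x[tr, , drop = FALSE], y[tr]),
      error = function(e) reference_cutpoints)
    best <- grid[[1L]]
    if (length(grid) > 1L) {
      inner_folds <- .stratified_folds(y[tr], inner, seed + f)
      scores <- vapply(grid, function(hp) {
        f1s <- vapply(seq_len(inner), function(g) {
          itr <- which(tr)[inner_folds != g]; ite <- which(tr)[inner_folds == g]
          if (length(unique(y[itr])) < 2L) return(NA_real_)
          pred <- .fit_predict(x[itr, , drop = FALSE], y[itr],
                               x[ite, , drop = FALSE], classifier, hp,
                               select_k, pca, balance, cutpoints, seed + f)
          compute_metrics(confusion_from_predictions(y[ite], pred))[["f1_minor"]]
        }, numeric(1))
        mean(f1s, na.rm = TRUE)
      }, numeric(1))
      best <- grid[[which.max(scores)]]
    }
    pred <- .fit_predict(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
                         classifier, best, select_k, pca, balance, cutpoints,
                         seed + f)
    cm <- confusion_from_predictions(y[te], pred)
    pooled <- pooled + c(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
    fold_metrics[[f]] <- compute_metrics(cm)
  }
  m <- do.call(rbind, fold_metrics)
  structure(list(classifier = classifier, folds = m,
                 mean = colMeans(m), sd = apply(m, 2L, stats::sd),
                 confusion = do.call(confusion_matrix, as.list(pooled)),
                 outer = outer, inner = inner, seed = seed),
            class = "photomod_cv")
}

.fit_cutpoints_matrix <- function(x, y) {
  v <- x[y == "T", , drop = FALSE]
  v <- v[v > 0]
  if (length(v) < 4L) stop("too few nonzero scores")
  stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
}

#' @export
print.photomod_cv <- function(x, ...) {
  cat("Nested ", x$outer, "x", x$inner, " CV (", x$classifier, "):\n", sep = "")
  for (m in colnames(x$folds))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Wilcoxon signed-rank comparison of two cross-validation runs
#'
#' Thin wrapper over [stats::wilcox.test()] on paired per-fold values of one
#' metric.
#'
#' @param cv_a,cv_b `photomod_cv` objects with equal fold counts.
#' @param metric metric column to compare (default "mcc").
#' @return `htest` object.
#' @export
compare_cv <- function(cv_a, cv_b, metric = "mcc") {
  stats::wilcox.test(cv_a$folds[, metric], cv_b$folds[, metric],
                     paired = TRUE, exact = FALSE)
}

#' Majority-vote prediction for novel sequences
#'
#' A novel sequence is mapped into the collection through its similarity
#' hits (E-value at most `evalue_max`); each matched collection protein's
#' profile row is classified and the majority class wins.  An exact tie goes
#' to "F" (precision on the scarce positive class is preferred), and a
#' sequence with no usable match is `NOT_ASSIGNABLE` — such sequences are
#' taken not to come from a photosynthetic organism.
#'
#' @param novel_hits similarity data.frame: novel query ids vs collection
#'   protein ids.
#' @param model fitted `photomod`.
#' @param profile `discretized_profile` over the collection proteins
#'   (rownames = protein ids).
#' @param evalue_max maximum E-value of a usable match (default 1).
#' @return named character vector per novel query: "T", "F" or
#'   "NOT_ASSIGNABLE".
#' @export
predict_novel <- function(novel_hits, model, profile, evalue_max = 1) {
  queries <- unique(novel_hits$query_id)
  vapply(stats::setNames(queries, queries), function(q) {
    h <- novel_hits[novel_hits$query_id == q & novel_hits$evalue <= evalue_max, ]
    matches <- intersect(unique(h$subject_id), rownames(profile$x))
    if (length(matches) == 0L) return("NOT_ASSIGNABLE")
    votes <- as.character(predict(model, profile$x[matches, , drop = FALSE]))
    if (sum(votes == "T") > sum(votes == "F")) "T" else "F"
  }, character(1))
}

#' Nearest-hit sequence-similarity baseline
#'
#' Transfers the label of the best database hit (highest bitscore with
#' E-value at most `evalue_max`; ties by lower E-value then lexicographic
#' subject id).  Queries without a usable hit are `NOT_ASSIGNABLE`.
#'
#' @param queries query ids to predict.
#' @param hits similarity data.frame: queries vs database proteins.
#' @param db_labels named character vector ("T"/"F") over database proteins.
#' @param evalue_max maximum usable E-value (default 10).
#' @return named character vector per query.
#' @export
blast_baseline <- function(queries, hits, db_labels, evalue_max = 10) {
  vapply(stats::setNames(queries, queries), function(q) {
    h <- hits[hits$query_id == q & hits$evalue <= evalue_max &
                hits$subject_id %in% names(db_labels), , drop = FALSE]
    if (nrow(h) == 0L) return("NOT_ASSIGNABLE")
    h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
    unname(db_labels[h$subject_id[1L]])
  }, character(1))
}
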