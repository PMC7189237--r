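test_that("metric conventions: perfection, zero denominators, MCC symmetries", {
  m <- compute_metrics(confusion_matrix(10, 20, 0, 0))
  expect_equal(unname(m), c(1, 1, 1, 1, 1))
  # all-negative predictions: precision/recall/f1/mcc collapse to 0
  m0 <- compute_metrics(confusion_matrix(0, 20, 0, 5))
  expect_equal(m0[["precision"]], 0)
  expect_equal(m0[["f1_minor"]], 0)
  expect_equal(m0[["mcc"]], 0)
  expect_error(compute_metrics(confusion_matrix(-1, 0, 0, 0)), "non-negative")
  # MCC invariant under (tp<->tn, fp<->fn) and negated under prediction flip
  cm <- confusion_matrix(7, 40, 9, 3)
  expect_equal(compute_metrics(confusion_matrix(40, 7, 3, 9))[["mcc"]],
               compute_metrics(cm)[["mcc"]])
  expect_equal(compute_metrics(confusion_matrix(9, 3, 7, 40))[["mcc"]],
               -compute_metrics(cm)[["mcc"]])
})

test_that("gain ratio matches hand entropy arithmetic", {
  lab <- c("T", "T", "T", "T", "F", "F", "F", "F")
  expect_equal(gain_ratio(c(0, 0, 0, 0, 1, 1, 1, 1), lab), 1)
  expect_equal(gain_ratio(rep(2, 8), lab), 0)
  # 4-level feature: H(Y)=1, H(Y|A)=0.5, H(A)=2 -> GR = 0.25
  a <- c(0, 0, 1, 1, 2, 2, 3, 3)
  y <- c("T", "T", "T", "F", "F", "F", "F", "T")
  expect_equal(gain_ratio(a, y), 0.25)
  expect_error(gain_ratio(1:3, c("T", "F")), "mismatch")
})

test_that("feature ranking puts planted informative columns first", {
  set.seed(8)
  n <- 120L
  lab <- rep(c("T", "F"), each = n / 2)
  x <- cbind(signal1 = ifelse(lab == "T", 3L, 0L),
             signal2 = ifelse(lab == "T", 2L, 0L) + sample(0:1, n, TRUE),
             noise1 = sample(0:3, n, TRUE),
             noise2 = sample(0:3, n, TRUE))
  sel <- select_top_features(x, lab, 2L)
  expect_setequal(sel$columns, c("signal1", "signal2"))
  expect_equal(select_top_features(x, lab, 4L)$columns[1L], "signal1")
  expect_error(select_top_features(x, lab, 0L), "positive")
  expect_error(select_top_features(x, lab, 9L), "exceeds")
})

test_that("PCA keeps the component count given by the eigenvalue oracle", {
  set.seed(5)
  x <- matrix(rnorm(200), 20, 10)
  for (vr in c(0.5, 0.8, 0.95, 1)) {
    fit <- pca_reduce(x, vr)
    ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
    oracle_k <- which(cumsum(ev) / sum(ev) >= vr - 1e-12)[1L]
    expect_equal(fit$k, oracle_k)
  }
  # data on a line collapses to one component
  t <- rnorm(30)
  line <- cbind(t, 2 * t, -t)
  expect_equal(pca_reduce(line, 0.95)$k, 1L)
  # the fitted transform reproduces training scores on new data
  fit <- pca_reduce(x, 0.8)
  expect_equal(unname(predict(fit, x)), unname(fit$scores))
})

test_that("SMOTE interpolates inside the minority bounding box", {
  set.seed(3)
  x <- matrix(sample(0:3, 20 * 4, TRUE), 20, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  syn <- smote_oversample(x, rate = 100, seed = 2L)
  expect_equal(nrow(syn), 20L)
  expect_equal(colnames(syn), colnames(x))
  for (j in 1:4) {
    expect_gte(min(syn[, j]), min(x[, j]))
    expect_lte(max(syn[, j]), max(x[, j]))
  }
  # coincident minority points generate coincident synthetics
  xc <- matrix(2, 8, 3)
  expect_true(all(smote_oversample(xc, rate = 50, seed = 1L) == 2))
  expect_error(smote_oversample(x[1:4, ], k_neighbors = 5L), "minority")
})

test_that("balanced reweighting equalizes class mass and conserves the total", {
  lab <- c(rep("T", 257), rep("F", 772))
  w <- reweight_balanced(lab)
  expect_equal(sum(w), 1029)
  expect_equal(sum(w[lab == "T"]), sum(w[lab == "F"]))
  expect_equal(w[1L], 1029 / (2 * 257))
  expect_equal(unique(reweight_balanced(c("T", "F", "T", "F"))), 1)
  expect_error(reweight_balanced(rep("T", 5)), "both classes")
})

test_that("the photomod classifier separates a planted toy and is seed-stable", {
  set.seed(2)
  lab <- rep(c("T", "F"), each = 10)
  x <- cbind(a = ifelse(lab == "T", 3, 0), b = sample(0:3, 20, TRUE))
  colnames(x) <- c("a", "b")
  fit <- photomod(x, lab, seed = 4L)
  expect_s3_class(fit, "photomod")
  expect_equal(as.character(predict(fit, x)), lab)
  fit2 <- photomod(x, lab, seed = 4L)
  expect_identical(as.character(predict(fit2, x)), as.character(predict(fit, x)))
  # svm and naive Bayes paths also fit and predict the separable toy
  for (clf in c("svm", "nb")) {
    f <- photomod(x, lab, classifier = clf, seed = 4L)
    expect_equal(as.character(predict(f, x)), lab)
  }
  expect_error(photomod(x, rep("Q", 20)), "T or F")
  # unseen columns are dropped, missing ones zero-filled
  xn <- cbind(x, z = 1)[, c("z", "a")]
  expect_length(predict(fit, xn), 20L)
})

test_that("novel-sequence majority voting follows the match and tie rules", {
  prof <- structure(list(
    x = matrix(c(3, 3, 0, 0), 4, 1, dimnames = list(paste0("p", 1:4), "a")),
    labels = c(p1 = "T", p2 = "T", p3 = "F", p4 = "F"),
    cutpoints = reference_cutpoints), class = "discretized_profile")
  model <- photomod(prof$x, prof$labels, ntree = 50L, seed = 1L)
  hits <- make_hits(list(q = "n1", s = "p1", e = 1e-5),
                    list(q = "n1", s = "p2", e = 1e-5),
                    list(q = "n1", s = "p3", e = 1e-5),
                    list(q = "n2", s = "p1", e = 5),     # above evalue_max
                    list(q = "n3", s = "p1", e = 1e-5),
                    list(q = "n3", s = "p3", e = 1e-5))
  pred <- predict_novel(hits, model, prof, evalue_max = 1)
  expect_equal(unname(pred["n1"]), "T")               # votes T,T,F
  expect_equal(unname(pred["n2"]), "NOT_ASSIGNABLE")  # no usable match
  expect_equal(unname(pred["n3"]), "F")               # tie goes to F
})

test_that("the similarity baseline transfers the best hit's label", {
  db <- c(d1 = "T", d2 = "F", d3 = "F")
  hits <- make_hits(list(q = "q1", s = "d1", e = 1e-30, bit = 300),
                    list(q = "q1", s = "d2", e = 1e-50, bit = 200),
                    list(q = "q2", s = "d2", e = 20, bit = 100),
                    list(q = "q3", s = "d2", e = 1e-10, bit = 150),
                    list(q = "q3", s = "d3", e = 1e-12, bit = 150))
  pred <- blast_baseline(c("q1", "q2", "q3", "q4"), hits, db)
  expect_equal(unname(pred["q1"]), "T")               # highest bitscore wins
  expect_equal(unname(pred["q2"]), "NOT_ASSIGNABLE")  # only hit above cutoff
  expect_equal(unname(pred["q3"]), "F")               # bit tie -> lower evalue (d3)
  expect_equal(unname(pred["q4"]), "NOT_ASSIGNABLE")
  # unassignable predictions count against the method
  cm <- confusion_from_predictions(c("T", "T"), c("NOT_ASSIGNABLE", "T"))
  expect_equal(cm$fn, 1L)
  expect_equal(cm$tp, 1L)
})

test_that("nested cross-validation is reproducible and aces a separable profile", {
  set.seed(6)
  n <- 60L
  lab <- rep(c("T", "F"), each = n / 2)
  x <- cbind(s1 = ifelse(lab == "T", stats::runif(n, 3, 5), 0),
             s2 = ifelse(lab == "T", stats::runif(n, 2, 4), 0),
             n1 = stats::runif(n, 0, 0.2))
  colnames(x) <- paste0("1e-10:F", 1:3)
  rownames(x) <- sprintf("p%02d", seq_len(n))
  prof <- structure(list(x = x,
                         columns = data.frame(threshold_tag = "1e-10",
                                              neighbor_family = paste0("F", 1:3),
                                              name = colnames(x)),
                         labels = stats::setNames(lab, rownames(x))),
                    class = "neighborhood_profile")
  grid <- list(list(ntree = 60L))
  cv1 <- nested_cv(prof, outer = 5L, inner = 2L, grid = grid, seed = 3L)
  cv2 <- nested_cv(prof, outer = 5L, inner = 2L, grid = grid, seed = 3L)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$mean[["accuracy"]], 1)
  expect_equal(nrow(cv1$folds), 5L)
  # balancing variants keep working end to end
  for (bal in c("smote", "reweight")) {
    cvb <- nested_cv(prof, outer = 3L, inner = 2L, grid = grid,
                     balance = bal, seed = 3L)
    expect_gte(cvb$mean[["mcc"]], 0.9)
  }
  # Wilcoxon comparison runs as a thin wrapper
  expect_s3_class(compare_cv(cv1, cv2), "htest")
})
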