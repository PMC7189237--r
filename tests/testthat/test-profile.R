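make_profile <- function(x, labels) {
  cols <- strsplit(colnames(x), ":", fixed = TRUE)
  structure(list(x = x,
                 columns = data.frame(threshold_tag = vapply(cols, `[`, "", 1L),
                                      neighbor_family = vapply(cols, `[`, "", 2L),
                                      name = colnames(x), stringsAsFactors = FALSE),
                 labels = labels),
            class = "neighborhood_profile")
}

test_that("quartile cutpoints use type-7 interpolation on positive nonzero scores", {
  x <- matrix(c(1, 2, 3, 4, 0, 9), nrow = 2, byrow = FALSE,
              dimnames = list(c("p1", "p2"), paste0("1e-10:F", 1:3)))
  prof <- make_profile(x, c(p1 = "T", p2 = "T"))
  # nonzero scores {1,2,3,4,9} over positives? p1 row: 1,3,0 ; p2: 2,4,9
  q <- fit_quartile_cutpoints(prof)
  expect_equal(unname(q), unname(stats::quantile(c(1, 2, 3, 4, 9), c(.25, .75))))

  x2 <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("p1", "p2"), paste0("1e-10:F", 1:2)))
  prof2 <- make_profile(x2, c(p1 = "T", p2 = "T"))
  expect_equal(unname(fit_quartile_cutpoints(prof2)), c(1.75, 3.25))

  # all-equal scores collapse both quartiles
  x3 <- matrix(2, 2, 2, dimnames = list(c("p1", "p2"), paste0("1e-10:F", 1:2)))
  expect_equal(unname(fit_quartile_cutpoints(make_profile(x3, c(p1 = "T", p2 = "T")))),
               c(2, 2))
  # too few nonzero scores in scope
  x4 <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("p1", "p2"), paste0("1e-10:F", 1:2)))
  expect_error(fit_quartile_cutpoints(make_profile(x4, c(p1 = "T", p2 = "F"))),
               "at least 4")
})

test_that("discretization maps scores to the four conservation levels", {
  x <- matrix(c(0, 0.3, 1.0, 3.0, reference_cutpoints[["q1"]], 2.61799),
              nrow = 1, dimnames = list("p", paste0("1e-10:F", 1:6)))
  prof <- make_profile(x, c(p = "T"))
  d <- discretize_profile(prof)
  expect_equal(unname(d$x[1, ]), c(0L, 1L, 2L, 3L, 1L, 2L))  # boundaries inclusive
  expect_error(discretize_profile(make_profile(matrix(-1, 1, 1,
    dimnames = list("p", "1e-10:F1")), c(p = "T"))), "negative")

  # monotone: v <= w implies level(v) <= level(w)
  set.seed(1)
  v <- sort(c(0, stats::runif(9999, 0, 6)))
  lv <- discretize_profile(make_profile(matrix(v, nrow = 1,
    dimnames = list("p", paste0("1e-10:F", seq_along(v)))), c(p = "T")))$x[1, ]
  expect_true(all(diff(lv) >= 0))
})

test_that("deduplication collapses identical instances, keeps label conflicts, is idempotent", {
  x <- matrix(c(1, 2,
                1, 2,
                1, 2,
                3, 0), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), paste0("1e-10:F", 1:2)))
  prof <- discretize_profile(make_profile(x, c(p1 = "T", p2 = "T", p3 = "F", p4 = "F")),
                             c(0.5, 1.5))
  dd <- deduplicate_profile(prof)
  expect_equal(nrow(dd$x), 3L)                      # p1/p2 collapse
  expect_equal(attr(dd, "n_removed"), 1L)
  expect_equal(sum(attr(dd, "conflict")), 2L)       # T/F conflict rows flagged
  dd2 <- deduplicate_profile(dd)
  expect_equal(dd2$x, dd$x)
  expect_equal(attr(dd2, "n_removed"), 0L)
})

test_that("ARFF export declares nominal attributes and round-trips", {
  x <- matrix(c(0L, 1L, 3L, 2L, 0L, 1L), nrow = 3,
              dimnames = list(paste0("p", 1:3), c("1e-10:F001", "1e-50:F002")))
  prof <- structure(list(x = x, columns = NULL,
                         labels = c(p1 = "T", p2 = "F", p3 = "T"),
                         cutpoints = reference_cutpoints),
                    class = "discretized_profile")
  path <- withr::local_tempfile(fileext = ".arff")
  write_arff(prof, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "@attribute")), 3L)  # 2 features + class
  expect_true(any(grepl("\\{0,1,2,3\\}", lines)))
  back <- read_arff_profile(path)
  expect_equal(unname(back$x), unname(x))
  expect_equal(unname(back$labels), unname(prof$labels))
  expect_equal(back$columns$threshold_tag, c("1e-10", "1e-50"))

  empty <- prof; empty$x <- x[0, , drop = FALSE]; empty$labels <- character(0)
  expect_error(write_arff(empty, path), "empty")
})

test_that("combined-threshold profiles restrict to their single-threshold parts", {
  gen <- generate_collection(synth_config(n_genomes = 5L, n_families = 40L,
                                          n_positive_families = 5L,
                                          n_negative_instances = 20L, seed = 9L))
  parts <- cluster_families(gen$hits, gen$collection, c(1e-10, 1e-50))
  cl <- call_neighborhoods(gen$collection)
  dm <- genome_distance_matrix(gen$hits, gen$collection)
  scored <- lapply(parts, function(p) score_adjacencies(adjacency_evidence(cl, p), dm))
  queries <- names(gen$labels)
  combined <- build_profile(queries, parts, scored, gen$labels)
  single <- build_profile(queries, parts["1e-10"], scored["1e-10"], gen$labels)
  sub <- combined$x[, combined$columns$threshold_tag == "1e-10", drop = FALSE]
  expect_equal(sub, single$x)
  expect_true(all(combined$x >= 0))
  # no all-zero columns survive
  expect_true(all(colSums(combined$x) > 0))
  # a query whose family has no scored neighbor gets an all-zero row
  zeroes <- rowSums(combined$x) == 0
  expect_true(any(!zeroes))   # planted positives are scored
})
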