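#' Reference quartile cutpoints
#'
#' Quartile cutpoints of the Phylo-score distribution over the conserved
#' neighbors of the photosynthetic proteins in the original 154-genome
#' prokaryote collection.  They are shipped as defaults for discretizing
#' profiles when no training data is available to refit them.
#' @format numeric vector `c(q1, q3)`.
#' @export
reference_cutpoints <- c(q1 = 0.41079, q3 = 2.61799)

#' Assemble the genome-neighborhood profile
#'
#' For each query protein and each E-value stringency, the feature value in
#' column (threshold, neighbor family c) is the Phylo score of the adjacency
#' between the query's family at that threshold and c, or 0 when the
#' adjacency is unscored (absent, or seen in fewer than three genomes).
#' Features from different thresholds occupy distinct namespaced columns;
#' the column universe is every neighbor family scored for at least one
#' query.  All-zero columns are dropped.
#'
#' @param queries character vector of query protein ids.
#' @param partitions named list of `family_partition` (one per threshold).
#' @param scored named list (same names) of scored adjacency data.frames
#'   ([score_adjacencies()]).
#' @param labels optional named vector of class labels ("T"/"F") per query;
#'   missing queries are "UNLABELED".
#' @return `neighborhood_profile`: list with `x` (numeric matrix queries x
#'   features), `columns` (data.frame threshold_tag, neighbor_family, name)
#'   and `labels`.
#' @export
build_profile <- function(queries, partitions, scored, labels = NULL) {
  stopifnot(length(partitions) >= 1L, identical(names(partitions), names(scored)))
  queries <- unique(queries)
  blocks <- list(); colinfo <- list()
  for (tag in names(partitions)) {
    fam_of <- partitions[[tag]]$family_of
    if (any(!queries %in% names(fam_of)))
      stop("query protein absent from partition ", tag, ": ",
           queries[!queries %in% names(fam_of)][1L])
    qfam <- fam_of[queries]
    sc <- scored[[tag]]
    sc <- sc[!is.na(sc$score) & sc$query_family %in% qfam, , drop = FALSE]
    nbr <- sort(unique(sc$neighbor_family))
    if (length(nbr) == 0L) next
    m <- matrix(0, nrow = length(queries), ncol = length(nbr),
                dimnames = list(queries, nbr))
    if (nrow(sc))
      for (k in seq_len(nrow(sc)))
        m[qfam == sc$query_family[k], sc$neighbor_family[k]] <- sc$score[k]
    keep <- colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0L) next
    colnames(m) <- paste(tag, colnames(m), sep = ":")
    blocks[[tag]] <- m
    colinfo[[tag]] <- data.frame(threshold_tag = tag,
                                 neighbor_family = nbr[keep],
                                 name = colnames(m),
                                 stringsAsFactors = FALSE)
  }
  x <- if (length(blocks)) do.call(cbind, blocks)
       else matrix(0, nrow = length(queries), ncol = 0L,
                   dimnames = list(queries, NULL))
  lab <- rep("UNLABELED", length(queries))
  names(lab) <- queries
  if (!is.null(labels)) {
    common <- intersect(queries, names(labels))
    lab[common] <- as.character(labels[common])
  }
  structure(list(x = x,
                 columns = if (length(colinfo)) do.call(rbind, c(colinfo, make.row.names = FALSE))
                           else data.frame(threshold_tag = character(),
                                           neighbor_family = character(),
                                           name = character()),
                 labels = lab),
            class = "neighborhood_profile")
}

#' @export
print.neighborhood_profile <- function(x, ...) {
  cat("Genome neighborhood profile:", nrow(x$x), "queries x", ncol(x$x),
      "features (", sum(x$labels == "T"), "T /", sum(x$labels == "F"), "F )\n")
  invisible(x)
}

#' Fit quartile cutpoints for Phylo-score discretization
#'
#' First and third quartiles (type-7, linear interpolation) of the nonzero
#' Phylo scores, by default restricted to positive-labeled instances — the
#' conservation scale is calibrated on the class of interest.
#'
#' @param profile `neighborhood_profile`.
#' @param scope `"positives"` (default) or `"all"`.
#' @return numeric `c(q1 = ..., q3 = ...)`.
#' @export
fit_quartile_cutpoints <- function(profile, scope = c("positives", "all")) {
  scope <- match.arg(scope)
  rows <- if (scope == "positives") profile$labels == "T" else rep(TRUE, nrow(profile$x))
  v <- profile$x[rows, , drop = FALSE]
  v <- v[v > 0]
  if (length(v) < 4L)
    stop("need at least 4 nonzero Phylo scores in scope to fit quartiles")
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = q[1L], q3 = q[2L])
}

#' Discretize a profile to conservation levels 0-3
#'
#' Level 0: score = 0 (no conservation); level 1: `0 < v <= q1` (low);
#' level 2: `q1 < v <= q3` (intermediate); level 3: `v > q3` (strong).
#'
#' @param profile `neighborhood_profile`.
#' @param cutpoints numeric `c(q1, q3)` with `q1 <= q3` (default the shipped
#'   [reference_cutpoints]).
#' @return `discretized_profile`: same shape, integer levels, cutpoints kept
#'   in the object.
#' @export
discretize_profile <- function(profile, cutpoints = reference_cutpoints) {
  q1 <- cutpoints[[1L]]; q3 <- cutpoints[[2L]]
  stopifnot(q1 <= q3)
  if (any(profile$x < 0)) stop("negative Phylo score in profile")
  lv <- matrix(0L, nrow(profile$x), ncol(profile$x), dimnames = dimnames(profile$x))
  lv[profile$x > 0 & profile$x <= q1] <- 1L
  lv[profile$x > q1 & profile$x <= q3] <- 2L
  lv[profile$x > q3] <- 3L
  structure(list(x = lv, columns = profile$columns, labels = profile$labels,
                 cutpoints = c(q1 = q1, q3 = q3)),
            class = "discretized_profile")
}

#' @export
print.discretized_profile <- function(x, ...) {
  cat("Discretized neighborhood profile:", nrow(x$x), "queries x", ncol(x$x),
      "features; cutpoints q1 =", x$cutpoints[["q1"]],
      ", q3 =", x$cutpoints[["q3"]], "\n")
  invisible(x)
}

#' Remove redundant instances from a discretized profile
#'
#' Instances identical in both feature vector and label collapse to one.
#' Instances identical in features but conflicting in label are all kept and
#' flagged.  Idempotent.
#'
#' @param profile `discretized_profile`.
#' @return deduplicated `discretized_profile` with attributes `n_removed`
#'   (count of collapsed rows) and `conflict` (logical per kept row).
#' @export
deduplicate_profile <- function(profile) {
  feat_key <- apply(profile$x, 1L, paste, collapse = ",")
  full_key <- paste(feat_key, profile$labels, sep = "|")
  keep <- !duplicated(full_key)
  out <- profile
  out$x <- profile$x[keep, , drop = FALSE]
  out$labels <- profile$labels[keep]
  fk <- feat_key[keep]
  conflict <- fk %in% fk[duplicated(fk)]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "conflict") <- conflict
  out
}

#' Write a discretized profile as ARFF
#'
#' Weka-dialect ARFF: each feature is a nominal attribute with levels
#' `{0,1,2,3}`, the class attribute is nominal `{T,F}`.  Attribute order
#' follows the profile's column order.
#'
#' @param profile `discretized_profile` with at least one instance.
#' @param path output file.
#' @param relation relation name.
#' @export
write_arff <- function(profile, path, relation = "genome_neighborhood_profile") {
  if (nrow(profile$x) == 0L) stop("cannot write an empty profile")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@relation ", relation), con)
  for (nm in colnames(profile$x))
    writeLines(sprintf("@attribute '%s' {0,1,2,3}", nm), con)
  writeLines("@attribute class {T,F}", con)
  writeLines("@data", con)
  lab <- ifelse(profile$labels %in% c("T", "F"), profile$labels, "?")
  writeLines(paste(apply(profile$x, 1L, paste, collapse = ","), lab, sep = ","), con)
  invisible(path)
}

#' Read a discretized profile from ARFF
#' @param path ARFF file written by [write_arff()].
#' @return `discretized_profile` (cutpoints unknown, set to NA).
#' @export
read_arff_profile <- function(path) {
  df <- foreign::read.arff(path)
  class_col <- names(df) == "class"
  x <- as.matrix(as.data.frame(lapply(df[, !class_col, drop = FALSE],
                                      function(v) as.integer(as.character(v)))))
  colnames(x) <- names(df)[!class_col]
  rownames(x) <- NULL
  labels <- as.character(df$class)
  labels[is.na(labels)] <- "UNLABELED"
  cols <- strsplit(colnames(x), ":", fixed = TRUE)
  structure(list(x = x,
                 columns = data.frame(
                   threshold_tag = vapply(cols, `[`, "", 1L),
                   neighbor_family = vapply(cols, `[`, "", 2L),
                   name = colnames(x), stringsAsFactors = FALSE),
                 labels = labels,
                 cutpoints = c(q1 = NA_real_, q3 = NA_real_)),
            class = "discretized_profile")
}

#' Write a profile (numeric or discretized) as CSV
#' @param profile `neighborhood_profile` or `discretized_profile`.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(query = rownames(profile$x), profile$x,
                   class = profile$labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
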