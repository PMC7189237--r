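#' Semantic F1 between two GO term sets
#'
#' Ancestor closure is applied to both sets; precision is the fraction of
#' the neighbor closure shared with the query closure, recall the fraction
#' of the query closure shared with the neighbor closure, and F1 their
#' harmonic mean.
#'
#' @param query_terms,neighbor_terms GO id vectors (nonempty).
#' @param dag `go_dag`.
#' @return F1 in `[0, 1]`.
#' @export
go_f1 <- function(query_terms, neighbor_terms, dag) {
  cq <- ancestor_closure(query_terms, dag)
  cn <- ancestor_closure(neighbor_terms, dag)
  if (length(cq) == 0L || length(cn) == 0L)
    stop("empty term set after ancestor closure")
  inter <- length(intersect(cq, cn))
  precision <- inter / length(cn)
  recall <- inter / length(cq)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' GO-coherence curve over Phylo-score cutoffs
#'
#' Quantifies how functionally similar conserved neighbors are to their
#' queries as neighborhood conservation becomes more stringent.  At each
#' cutoff, neighbors whose Phylo score falls below it are dropped; each
#' covered query's annotation is compared (semantic F1 on ancestor-closed
#' sets) against the union of its surviving neighbors' terms, and the mean
#' over covered queries is reported.  The random baseline repeats the
#' computation with the neighbor term set replaced by an equal-size uniform
#' sample from the pool of all annotated GO terms, averaged over `n_random`
#' draws.
#'
#' @param neighbor_scores data.frame with columns `query` (protein id),
#'   `neighbor` (protein id) and `score` (Phylo score of the adjacency
#'   supporting the pair).
#' @param annotations named list: protein id -> GO id vector.
#' @param dag `go_dag`.
#' @param cutoffs increasing numeric vector of Phylo-score cutoffs.
#' @param n_random random draws per cutoff (default 20).
#' @param seed integer seed for the random baseline.
#' @return data.frame: cutoff, f1_neighbors, f1_random, coverage (number of
#'   covered queries; F1 columns are `NA` where coverage is 0).
#' @export
coherence_curve <- function(neighbor_scores, annotations, dag, cutoffs,
                            n_random = 20L, seed = 1L) {
  pool <- unlist(annotations, use.names = FALSE)
  stopifnot(length(pool) > 0L)
  .with_seed(seed, {
    rows <- lapply(cutoffs, function(ct) {
      kept <- neighbor_scores[neighbor_scores$score >= ct, , drop = FALSE]
      queries <- unique(kept$query)
      queries <- queries[vapply(queries, function(q)
        length(annotations[[q]] %||% character(0)) > 0L, logical(1))]
      f1n <- f1r <- NA_real_
      if (length(queries)) {
        per_query <- vapply(queries, function(q) {
          nbrs <- kept$neighbor[kept$query == q]
          nterms <- unique(unlist(annotations[nbrs], use.names = FALSE))
          if (length(nterms) == 0L) return(c(NA_real_, NA_real_))
          f1 <- go_f1(annotations[[q]], nterms, dag)
          rnd <- mean(vapply(seq_len(n_random), function(i) {
            go_f1(annotations[[q]], sample(pool, length(nterms), replace = FALSE),
                  dag)
          }, numeric(1)))
          c(f1, rnd)
        }, numeric(2))
        covered <- !is.na(per_query[1L, ])
        queries <- queries[covered]
        if (any(covered)) {
          f1n <- mean(per_query[1L, covered])
          f1r <- mean(per_query[2L, covered])
        }
      }
      data.frame(cutoff = ct, f1_neighbors = f1n, f1_random = f1r,
                 coverage = length(queries))
    })
    do.call(rbind, rows)
  })
}
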