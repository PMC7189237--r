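#' Build a sequence-similarity network at one E-value threshold
#'
#' An undirected edge joins two distinct proteins when at least one hit in
#' either direction has `evalue <= threshold`; the edge weight is the maximum
#' bitscore over the qualifying hits.  Self-hits are ignored.
#'
#' @param hits similarity data.frame ([read_similarity_table()]).
#' @param evalue_threshold strictly positive E-value cutoff.
#' @param proteins optional character vector of protein ids to include as
#'   vertices even when isolated (defaults to the ids present in `hits`).
#' @return igraph undirected weighted graph.
#' @export
build_ssn <- function(hits, evalue_threshold, proteins = NULL) {
  stopifnot(evalue_threshold > 0)
  keep <- hits$evalue <= evalue_threshold & hits$query_id != hits$subject_id
  h <- hits[keep, c("query_id", "subject_id", "bitscore"), drop = FALSE]
  if (is.null(proteins))
    proteins <- sort(unique(c(hits$query_id, hits$subject_id)))
  else
    proteins <- sort(unique(proteins))
  if (nrow(h)) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste(a, b, sep = "\r")
    w <- tapply(h$bitscore, key, max)
    ab <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(ab, `[`, "", 1L),
                        b = vapply(ab, `[`, "", 2L),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(), b = character(), weight = numeric())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = proteins))
  g
}

#' Markov clustering of a weighted graph into protein families
#'
#' Classic MCL on the column-stochastic transition matrix with self-loops:
#' expansion (matrix squaring) alternates with inflation (entrywise power
#' `inflation`, then column renormalisation) until the matrix change drops
#' below `tol` or `max_iter` is reached.  Clusters are read from the limit
#' matrix's attractor structure (connected components of its support), so a
#' cluster can never span two disconnected components of the input graph.
#' Isolated vertices become singleton families.
#'
#' @param graph igraph undirected weighted graph (from [build_ssn()]).
#' @param inflation inflation exponent, > 1 (default 2).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the max absolute entry change.
#' @param self_loop per-vertex self-loop weight; default `"max"` uses each
#'   vertex's maximum incident edge weight (1 for isolated vertices).
#' @param prune entries below this are zeroed each iteration.
#' @param threshold_tag string used in family ids (e.g. "1e-10").
#' @return A `family_partition`: list with `threshold_tag`, `family_of`
#'   (named character vector protein -> family id), `families` (named list of
#'   member vectors) and `converged` flag.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100L, tol = 1e-6,
                        self_loop = "max", prune = 1e-9, threshold_tag = "t") {
  stopifnot(inflation > 1)
  nodes <- sort(igraph::V(graph)$name)
  n <- length(nodes)
  if (n == 0L) return(.new_partition(character(0), threshold_tag, TRUE))
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph)) "weight" else NULL,
                                   sparse = TRUE)
  A <- A[nodes, nodes, drop = FALSE]
  A <- methods::as(A, "generalMatrix")
  loops <- if (identical(self_loop, "max")) {
    m <- apply(A, 2L, max)
    ifelse(m > 0, m, 1)
  } else rep(as.numeric(self_loop), n)
  M <- A + Matrix::Diagonal(n, loops)
  M <- .col_normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2@x <- M2@x^inflation              # inflation
    M2 <- Matrix::drop0(M2, tol = prune)
    M2 <- .col_normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")
  support <- M != 0
  support <- support | Matrix::t(support)
  g2 <- igraph::graph_from_adjacency_matrix(support, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g2)$membership
  part <- .membership_to_partition(stats::setNames(comp, nodes), threshold_tag)
  part$converged <- converged
  part
}

.col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(length(cs), 1 / cs)
}

.membership_to_partition <- function(membership, threshold_tag) {
  nodes <- names(membership)
  # canonical family indexing: order groups by their smallest member id
  groups <- split(nodes, membership)
  groups <- groups[order(vapply(groups, min, ""))]
  fam_ids <- sprintf("F%s_%04d", threshold_tag, seq_along(groups))
  family_of <- character(length(nodes))
  names(family_of) <- nodes
  for (i in seq_along(groups)) family_of[groups[[i]]] <- fam_ids[i]
  structure(list(threshold_tag = threshold_tag,
                 family_of = family_of[sort(nodes)],
                 families = stats::setNames(lapply(groups, sort), fam_ids),
                 converged = TRUE),
            class = "family_partition")
}

.new_partition <- function(nodes, tag, converged) {
  structure(list(threshold_tag = tag,
                 family_of = stats::setNames(character(0), character(0)),
                 families = list(), converged = converged),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  cat("Protein family partition @", x$threshold_tag, ":",
      length(x$families), "families over", length(x$family_of), "proteins\n")
  invisible(x)
}

#' Partition proteins into families at several E-value stringencies
#'
#' Runs [build_ssn()] + [mcl_cluster()] once per threshold over the whole
#' collection's proteome.
#'
#' @param hits similarity data.frame.
#' @param collection `genome_collection` (defines the protein universe).
#' @param thresholds numeric E-value cutoffs (default `c(1e-10, 1e-50, 1e-100)`).
#' @param ... passed to [mcl_cluster()].
#' @return named list of `family_partition` objects, one per threshold; names
#'   are the threshold tags.
#' @export
cluster_families <- function(hits, collection,
                             thresholds = c(1e-10, 1e-50, 1e-100), ...) {
  proteins <- names(collection$protein_lengths)
  out <- lapply(thresholds, function(th) {
    tag <- threshold_tag(th)
    g <- build_ssn(hits, th, proteins = proteins)
    mcl_cluster(g, threshold_tag = tag, ...)
  })
  stats::setNames(out, vapply(thresholds, threshold_tag, ""))
}

#' Canonical tag for an E-value threshold ("1e-10" style)
#' @param threshold numeric E-value.
#' @return character tag.
#' @export
threshold_tag <- function(threshold) {
  sub("e-0", "e-", formatC(threshold, format = "e", digits = 0), fixed = TRUE)
}

#' Reciprocal best hits between two genomes
#'
#' A pair (p, q) is kept when q is p's best hit among genome-b subjects and p
#' is q's best hit among genome-a subjects.  "Best" means highest bitscore,
#' ties broken by lower E-value, then lexicographically smaller subject id.
#'
#' @param hits similarity data.frame.
#' @param collection `genome_collection`.
#' @param genome_a,genome_b distinct genome ids.
#' @return data.frame with columns protein_a, protein_b.
#' @export
reciprocal_best_hits <- function(hits, collection, genome_a, genome_b) {
  stopifnot(genome_a != genome_b)
  gmap <- stats::setNames(collection$genes$genome_id, collection$genes$protein_id)
  ab <- .best_hits(hits, gmap, genome_a, genome_b)
  ba <- .best_hits(hits, gmap, genome_b, genome_a)
  key_ab <- paste(ab$query, ab$best, sep = "\r")
  key_ba <- paste(ba$best, ba$query, sep = "\r")
  keep <- key_ab %in% key_ba
  out <- data.frame(protein_a = ab$query[keep], protein_b = ab$best[keep],
                    stringsAsFactors = FALSE)
  out[order(out$protein_a), , drop = FALSE]
}

# best subject in genome `to` for every query protein of genome `from`
.best_hits <- function(hits, gmap, from, to) {
  qg <- gmap[hits$query_id]
  sg <- gmap[hits$subject_id]
  h <- hits[!is.na(qg) & !is.na(sg) & qg == from & sg == to &
              hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(query = character(), best = character()))
  o <- order(h$query_id, -h$bitscore, h$evalue, h$subject_id)
  h <- h[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  data.frame(query = h$query_id[first], best = h$subject_id[first],
             stringsAsFactors = FALSE)
}
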