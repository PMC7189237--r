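#' Shared gene content of two genomes
#'
#' The proportion `s` of shared gene content: the number of reciprocal best
#' hits divided by the average proteome size of the two genomes.
#'
#' @param n_rbh reciprocal-best-hit count.
#' @param size_a,size_b proteome sizes (> 0).
#' @return s in `[0, 1]`.
#' @export
shared_gene_content <- function(n_rbh, size_a, size_b) {
  stopifnot(size_a > 0, size_b > 0, n_rbh >= 0)
  s <- n_rbh / mean(c(size_a, size_b))
  if (s > 1) stop("shared gene content > 1: inconsistent RBH input")
  s
}

#' Genome-genome distance from shared gene content
#'
#' `d = -ln(s)`, capped at `d_max` so that completely disjoint genomes
#' (`s = 0`) get a finite distance.
#'
#' @param s shared gene content in `[0, 1]`.
#' @param d_max finite cap for the distance.
#' @return non-negative distance.
#' @export
genome_distance <- function(s, d_max) {
  if (s < 0 || s > 1) stop("shared gene content must lie in [0, 1]")
  if (s == 0) return(d_max)
  min(-log(s), d_max)
}

#' Pairwise genome distance matrix of a collection
#'
#' Computes reciprocal best hits for every genome pair, converts the RBH
#' count to shared gene content and then to the distance `d = -ln(s)`.  The
#' default cap for a pair is `-ln(1 / mean proteome size)` — the distance a
#' single shared gene would give — keeping `s = 0` finite without letting it
#' dominate the trees.
#'
#' @param hits similarity data.frame.
#' @param collection `genome_collection`.
#' @param d_max optional fixed cap overriding the per-pair default.
#' @return symmetric numeric matrix with zero diagonal, dimnames = genome ids.
#' @export
genome_distance_matrix <- function(hits, collection, d_max = NULL) {
  ids <- collection$genome_ids
  sizes <- proteome_sizes(collection)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    rbh <- reciprocal_best_hits(hits, collection, ids[i], ids[j])
    s <- shared_gene_content(nrow(rbh), sizes[ids[i]], sizes[ids[j]])
    cap <- if (is.null(d_max)) log(mean(c(sizes[ids[i]], sizes[ids[j]]))) else d_max
    d[i, j] <- d[j, i] <- genome_distance(s, cap)
  }
  d
}

#' Neighbor-joining tree over a genome subset
#'
#' Standard Saitou–Nei neighbor joining on the restricted distance matrix
#' (via \pkg{ape}); negative branch lengths are clamped to zero so that the
#' total branch length is a valid non-negative conservation measure.
#'
#' @param dm symmetric distance matrix with genome ids as dimnames.
#' @param genomes character vector of at least 3 genome ids present in `dm`.
#' @return `phylo` tree (ape) with clamped branch lengths.
#' @export
nj_tree <- function(dm, genomes = rownames(dm)) {
  genomes <- sort(unique(genomes))
  if (length(genomes) < 3L)
    stop("neighbor joining needs at least 3 genomes")
  missing <- setdiff(genomes, rownames(dm))
  if (length(missing))
    stop("genome(s) missing from distance matrix: ", paste(missing, collapse = ", "))
  tree <- ape::nj(stats::as.dist(dm[genomes, genomes]))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Total branch length of a tree
#' @param tree `phylo` object.
#' @return numeric sum of branch lengths.
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)

#' Phylo conservation score of one adjacency
#'
#' The score of a (query family, neighbor family) adjacency observed in a set
#' of genomes is the total branch length of the neighbor-joining tree over
#' exactly those genomes.  Adjacencies seen in fewer than three genomes are
#' not scored (returned as `NA`): conservation in one or two genomes is not
#' distinguishable from lineage-specific chance.
#'
#' @param genomes_observed genome ids in which the adjacency occurs.
#' @param dm full genome distance matrix.
#' @return non-negative score, or `NA_real_` when unscorable.
#' @export
phylo_score <- function(genomes_observed, dm) {
  genomes_observed <- unique(genomes_observed)
  if (length(genomes_observed) < 3L) return(NA_real_)
  total_branch_length(nj_tree(dm, genomes_observed))
}

#' Collect adjacency evidence between protein families
#'
#' For one family partition, records for every ordered pair of distinct
#' families (A, B) the set of genomes having at least one neighborhood
#' cluster that contains a member of each.  A genome counts once per pair no
#' matter how many clusters or copies support it.
#'
#' @param clusters neighborhood cluster assignment ([call_neighborhoods()]).
#' @param partition `family_partition`.
#' @return data.frame: query_family, neighbor_family, n_genomes, genomes
#'   (list column of genome id vectors).
#' @export
adjacency_evidence <- function(clusters, partition) {
  fam <- partition$family_of[clusters$protein_id]
  keep <- !is.na(fam)
  cl <- clusters[keep, , drop = FALSE]
  fam <- fam[keep]
  pieces <- split(data.frame(fam = fam, genome = cl$genome_id,
                             stringsAsFactors = FALSE),
                  cl$cluster_id)
  rows <- lapply(pieces, function(p) {
    fams <- sort(unique(p$fam))
    if (length(fams) < 2L) return(NULL)
    grid <- expand.grid(query_family = fams, neighbor_family = fams,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$query_family != grid$neighbor_family, , drop = FALSE]
    grid$genome <- p$genome[1L]
    grid
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(query_family = character(), neighbor_family = character(),
                      n_genomes = integer(), genomes = I(list()),
                      stringsAsFactors = FALSE))
  key <- paste(rows$query_family, rows$neighbor_family, sep = "\r")
  gsets <- lapply(split(rows$genome, key), function(g) sort(unique(g)))
  ks <- strsplit(names(gsets), "\r", fixed = TRUE)
  out <- data.frame(query_family = vapply(ks, `[`, "", 1L),
                    neighbor_family = vapply(ks, `[`, "", 2L),
                    n_genomes = lengths(gsets),
                    stringsAsFactors = FALSE)
  out$genomes <- I(unname(gsets))
  rownames(out) <- NULL
  out
}

#' Score all adjacencies of a partition
#'
#' Applies [phylo_score()] to each adjacency-evidence row; identical genome
#' sets share one tree computation.
#'
#' @param evidence data.frame from [adjacency_evidence()].
#' @param dm genome distance matrix covering all observed genomes.
#' @return the evidence data.frame with an added `score` column (`NA` for
#'   adjacencies in fewer than 3 genomes).
#' @export
score_adjacencies <- function(evidence, dm) {
  if (nrow(evidence) == 0L) {
    evidence$score <- numeric(0)
    return(evidence)
  }
  keys <- vapply(evidence$genomes, paste, "", collapse = "|")
  uk <- unique(keys)
  cache <- stats::setNames(vapply(uk, function(k) {
    phylo_score(strsplit(k, "|", fixed = TRUE)[[1L]], dm)
  }, numeric(1)), uk)
  evidence$score <- unname(cache[keys])
  evidence
}
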