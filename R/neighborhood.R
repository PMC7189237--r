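#' Call same-strand gene neighborhood clusters in one genome
#'
#' Consecutive genes on the same strand of the same contig are chained into
#' one cluster when their intergenic distance is at most `max_gap` bp or when
#' they overlap.  The intergenic distance between adjacent genes is
#' `next_start - prev_end - 1` (bases strictly between them); overlapping
#' genes (next_start <= prev_end) always chain.  A strand change or a larger
#' gap breaks the chain, so every gene lands in exactly one cluster
#' (singletons allowed).  Clusters never span contigs.
#'
#' @param genes data.frame of one genome's genes as returned by
#'   [genome_genes()] (sorted by contig, start).
#' @param max_gap maximum intergenic distance in bp (default 250).
#' @return data.frame of cluster assignments: columns genome_id, contig_id,
#'   cluster_id, gene_id, protein_id, strand, start, end; one row per gene,
#'   ordered by coordinate.
#' @export
call_same_strand_clusters <- function(genes, max_gap = 250L) {
  if (nrow(genes) == 0L)
    return(data.frame(genome_id = character(), contig_id = character(),
                      cluster_id = character(), gene_id = character(),
                      protein_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  stopifnot(length(unique(genes$genome_id)) == 1L)
  o <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  n <- nrow(genes)
  new_cluster <- rep(TRUE, n)
  if (n > 1L) {
    same_contig <- genes$contig_id[-1L] == genes$contig_id[-n]
    same_strand <- genes$strand[-1L] == genes$strand[-n]
    gap <- genes$start[-1L] - genes$end[-n] - 1L
    chain <- same_contig & same_strand & gap <= max_gap
    new_cluster[-1L] <- !chain
  }
  idx <- cumsum(new_cluster)
  data.frame(genome_id = genes$genome_id,
             contig_id = genes$contig_id,
             cluster_id = sprintf("%s_nc%04d", genes$genome_id[1L], idx),
             gene_id = genes$gene_id,
             protein_id = genes$protein_id,
             strand = genes$strand,
             start = genes$start,
             end = genes$end,
             stringsAsFactors = FALSE)
}

#' Merge head-to-head divergent neighborhood clusters
#'
#' Two adjacent strand-pure clusters whose transcription starts diverge (a
#' minus-strand cluster followed on the coordinate axis by a plus-strand
#' cluster, so the first gene of each faces away from the other) are merged
#' when the gap between the two first genes lies within `[min_gap, max_gap]`
#' bp, reflecting shared divergent promoter regions.  Merging is a single
#' left-to-right pass: a merged (mixed-strand) cluster does not merge again.
#'
#' @param clusters cluster assignment data.frame from
#'   [call_same_strand_clusters()].
#' @param min_gap,max_gap divergent-gap window in bp (defaults 200 and 1000).
#' @return cluster assignment data.frame of the same shape; merged clusters
#'   take the left cluster's id.
#' @export
merge_divergent_clusters <- function(clusters, min_gap = 200L, max_gap = 1000L) {
  if (nrow(clusters) == 0L) return(clusters)
  ids <- unique(clusters$cluster_id)
  info <- do.call(rbind, lapply(ids, function(cid) {
    cc <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    data.frame(cluster_id = cid, contig_id = cc$contig_id[1L],
               strand = if (length(unique(cc$strand)) == 1L) cc$strand[1L] else ".",
               start = min(cc$start), end = max(cc$end),
               stringsAsFactors = FALSE)
  }))
  info <- info[order(info$contig_id, info$start), , drop = FALSE]
  merged_into <- stats::setNames(info$cluster_id, info$cluster_id)
  i <- 1L
  while (i < nrow(info)) {
    a <- info[i, ]; b <- info[i + 1L, ]
    if (a$contig_id == b$contig_id && a$strand == "-" && b$strand == "+") {
      # first gene of the - cluster is its rightmost gene; first gene of the +
      # cluster its leftmost: the divergent gap is what separates the clusters
      gap <- b$start - a$end - 1L
      if (gap >= min_gap && gap <= max_gap) {
        merged_into[b$cluster_id] <- a$cluster_id
        i <- i + 2L          # single pass, no cascading
        next
      }
    }
    i <- i + 1L
  }
  clusters$cluster_id <- unname(merged_into[clusters$cluster_id])
  clusters
}

#' Call final neighborhood clusters for every genome of a collection
#'
#' @param collection `genome_collection`.
#' @param max_gap same-strand intergenic threshold (bp).
#' @param div_min,div_max divergent-merge window (bp).
#' @return data.frame of cluster assignments over the whole collection.
#' @export
call_neighborhoods <- function(collection, max_gap = 250L,
                               div_min = 200L, div_max = 1000L) {
  out <- lapply(collection$genome_ids, function(gid) {
    cl <- call_same_strand_clusters(genome_genes(collection, gid), max_gap = max_gap)
    merge_divergent_clusters(cl, min_gap = div_min, max_gap = div_max)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neighbor pairs implied by neighborhood clusters
#'
#' All unordered pairs of distinct genes co-occurring in one final cluster
#' (all-vs-all within cluster, not only immediate adjacency).
#'
#' @param clusters cluster assignment data.frame.
#' @param id_col which id to pair up: `"protein_id"` (default) or `"gene_id"`.
#' @return data.frame with columns a, b (a < b lexicographically) and
#'   genome_id.
#' @export
neighbor_pairs <- function(clusters, id_col = c("protein_id", "gene_id")) {
  id_col <- match.arg(id_col)
  pieces <- split(clusters, clusters$cluster_id)
  out <- lapply(pieces, function(cc) {
    ids <- sort(unique(cc[[id_col]]))
    if (length(ids) < 2L) return(NULL)
    cmb <- utils::combn(ids, 2L)
    data.frame(a = cmb[1L, ], b = cmb[2L, ], genome_id = cc$genome_id[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(a = character(), b = character(),
                      genome_id = character(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  unique(out)
}
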