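# small in-code fixtures shared across test files

# a one-genome gene table from (start, end, strand) triples
make_genes <- function(coords, genome_id = "g1", contig_id = "g1_c1") {
  n <- length(coords)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(gene_id = sprintf("gene_%s_%02d", genome_id, i),
               genome_id = genome_id, contig_id = contig_id,
               start = as.integer(coords[[i]][1L]),
               end = as.integer(coords[[i]][2L]),
               strand = as.character(coords[[i]][3L]),
               protein_id = sprintf("%s_p%02d", genome_id, i),
               stringsAsFactors = FALSE)
  }))
}

# a similarity hit row (both directions unless one_way)
make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r$q, subject_id = r$s,
               percent_identity = r$pid %||% 90,
               alignment_length = r$alen %||% 100L,
               evalue = r$e, bitscore = r$bit %||% 200,
               query_coverage = r$cov %||% 90,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny chain ontology: r <- n1 <- n2 <- ... (is_a edges child -> parent)
chain_dag <- function(n) {
  ids <- c("GO:r", paste0("GO:n", seq_len(n)))
  new_go_dag(data.frame(child = ids[-1L], parent = ids[-(n + 1L)]))
}

# independent brute-force MCL oracle: dense base-R matrices, hand BFS
oracle_mcl <- function(adj, inflation = 2, max_iter = 200, tol = 1e-6) {
  n <- nrow(adj)
  loops <- apply(adj, 2, max)
  loops[loops == 0] <- 1
  M <- adj + diag(loops, n)
  M <- sweep(M, 2, colSums(M), "/")
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-9] <- 0
    cs <- colSums(M2); cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  supp <- (M != 0) | t(M != 0)
  # hand-rolled connected components over the support
  comp <- rep(NA_integer_, n); cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    frontier <- v
    while (length(frontier)) {
      comp[frontier] <- cur
      nxt <- unique(unlist(lapply(frontier, function(u) which(supp[u, ]))))
      frontier <- nxt[is.na(comp[nxt])]
    }
  }
  comp
}

# do two integer label vectors describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
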