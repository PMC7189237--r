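#' Configuration for the synthetic genome-collection generator
#'
#' Defaults describe a small but realistic prokaryotic study condition: 10
#' genomes sharing 200 protein families, 20 of which are "photosynthetic"
#' query families flanked by planted conserved neighborhoods (3 dedicated
#' neighbor families each, carried by 90% of genomes), while the remaining
#' families are laid out in an independently shuffled order per genome.
#'
#' @param n_genomes number of genomes.
#' @param n_families number of protein families.
#' @param n_positive_families number of positive (photosynthetic) query
#'   families.
#' @param cluster_size planted cluster size including the query (default 4).
#' @param conservation_prob probability that a genome carries the planted
#'   cluster of a positive family intact.
#' @param decoy_conservation probability that a block of three free
#'   (negative) families co-occurs as a cluster in a genome; 0 (default)
#'   leaves negative contexts fully shuffled.
#' @param family_presence_prob probability that a non-query family is
#'   present in a genome at all.
#' @param intergenic_gap range (bp) of within-cluster intergenic gaps.
#' @param spacer_gap range (bp) of between-unit spacers (kept above the
#'   divergent-merge window).
#' @param random_adjacency_prob probability that a between-unit junction
#'   uses a within-cluster gap instead, creating chance adjacencies.
#' @param divergent_pair_prob probability that a junction falls in the
#'   divergent-merge window (200-1000 bp).
#' @param evalue_within log10 E-value range of within-family hits.
#' @param evalue_between log10 E-value range of between-family noise hits.
#' @param between_hit_prob per-protein expected number of between-family
#'   noise hits divided by 10.
#' @param protein_length range of protein lengths (aa).
#' @param n_negative_instances how many negative-family proteins to label
#'   "F" for model building.
#' @param go_noise probability that a protein's GO annotation is replaced
#'   by a random term from the pool.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return `synth_config` list.
#' @export
synth_config <- function(n_genomes = 10L, n_families = 200L,
                         n_positive_families = 20L, cluster_size = 4L,
                         conservation_prob = 0.9, decoy_conservation = 0,
                         family_presence_prob = 0.85,
                         intergenic_gap = c(20L, 200L),
                         spacer_gap = c(1100L, 3000L),
                         random_adjacency_prob = 0.25,
                         divergent_pair_prob = 0.05,
                         evalue_within = c(-160, -40),
                         evalue_between = c(-5, 1),
                         between_hit_prob = 0.02,
                         protein_length = c(80L, 300L),
                         n_negative_instances = 300L,
                         go_noise = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_positive_families <= cfg$n_families,
            cfg$conservation_prob >= 0, cfg$conservation_prob <= 1,
            cfg$cluster_size >= 2L)
  needed <- cfg$n_positive_families * cfg$cluster_size
  if (needed > cfg$n_families)
    stop("planted clusters need ", needed, " families but only ",
         cfg$n_families, " configured")
  structure(cfg, class = "synth_config")
}

#' Generate a fully self-consistent synthetic genome collection
#'
#' Produces genomes (gene coordinates + strands), protein sequences, an
#' all-vs-all similarity table, GO annotations over a small synthetic
#' ontology, class labels and the planted ground truth.  Within-family hits
#' get strong E-values and between-family hits weak ones, so the
#' similarity network plus Markov clustering at the loose threshold
#' recovers the planted families; planted clusters sit within the 250-bp
#' same-strand rule.
#'
#' @param config `synth_config`.
#' @return list with elements `collection` (`genome_collection`),
#'   `sequences` (named character), `hits` (similarity data.frame),
#'   `annotations` (named list protein -> GO ids), `dag` (`go_dag`),
#'   `photo_terms`, `labels` (named "T"/"F" vector over instance proteins)
#'   and `ground_truth`.
#' @export
generate_collection <- function(config = synth_config()) {
  .with_seed(config$seed, .generate_collection_impl(config))
}

.generate_collection_impl <- function(cfg) {
  fams <- sprintf("fam%03d", seq_len(cfg$n_families))
  n_pos <- cfg$n_positive_families
  k_nbr <- cfg$cluster_size - 1L
  pos_fams <- fams[seq_len(n_pos)]
  nbr_fams <- matrix(fams[n_pos + seq_len(n_pos * k_nbr)], nrow = n_pos,
                     byrow = TRUE, dimnames = list(pos_fams, NULL))
  free_fams <- fams[-seq_len(n_pos * (k_nbr + 1L))]
  decoy_blocks <- list()
  if (cfg$decoy_conservation > 0 && length(free_fams) >= 3L) {
    nb <- length(free_fams) %/% 3L
    decoy_blocks <- split(free_fams[seq_len(nb * 3L)], rep(seq_len(nb), each = 3L))
  }
  blocked_free <- unlist(decoy_blocks, use.names = FALSE)
  loose_free <- setdiff(free_fams, blocked_free)

  fam_len <- stats::setNames(
    sample(seq(cfg$protein_length[1L], cfg$protein_length[2L]), cfg$n_families,
           replace = TRUE), fams)
  genome_ids <- sprintf("g%02d", seq_len(cfg$n_genomes))

  genes <- list(); family_of <- character(); fires <- matrix(
    FALSE, cfg$n_genomes, n_pos, dimnames = list(genome_ids, pos_fams))

  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    present <- stats::setNames(stats::runif(cfg$n_families) < cfg$family_presence_prob, fams)
    present[pos_fams] <- TRUE
    units <- list()
    for (p in seq_len(n_pos)) {
      fired <- stats::runif(1) < cfg$conservation_prob
      fires[gi, p] <- fired
      if (fired) {
        units[[length(units) + 1L]] <- c(pos_fams[p], nbr_fams[p, ])
        present[nbr_fams[p, ]] <- FALSE   # consumed by the block
      } else {
        units[[length(units) + 1L]] <- pos_fams[p]
      }
    }
    for (b in decoy_blocks) {
      if (any(present[b]) && stats::runif(1) < cfg$decoy_conservation) {
        units[[length(units) + 1L]] <- b
        present[b] <- FALSE
      }
    }
    singles <- names(present)[present & !(names(present) %in% pos_fams)]
    units <- c(units, as.list(singles))
    units <- units[sample.int(length(units))]

    pos_bp <- 1L; rows <- list()
    for (u in units) {
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      for (j in seq_along(u)) {
        fam <- u[[j]]
        glen <- 3L * fam_len[[fam]]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = paste0("gene_", gid, ".", fam),
          genome_id = gid, contig_id = paste0(gid, "_c1"),
          start = pos_bp, end = pos_bp + glen - 1L, strand = strand,
          protein_id = paste0(gid, ".", fam), stringsAsFactors = FALSE)
        family_of[paste0(gid, ".", fam)] <- fam
        gap <- if (j < length(u))
          sample(seq(cfg$intergenic_gap[1L], cfg$intergenic_gap[2L]), 1L)
        else {
          u01 <- stats::runif(1)
          if (u01 < cfg$random_adjacency_prob)
            sample(seq(cfg$intergenic_gap[1L], cfg$intergenic_gap[2L]), 1L)
          else if (u01 < cfg$random_adjacency_prob + cfg$divergent_pair_prob)
            sample(300:900, 1L)
          else sample(seq(cfg$spacer_gap[1L], cfg$spacer_gap[2L]), 1L)
        }
        pos_bp <- pos_bp + glen + gap
      }
    }
    genes[[gi]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, genes)

  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  fam_seq <- lapply(fams, function(f)
    paste(sample(aa, fam_len[[f]], replace = TRUE), collapse = ""))
  names(fam_seq) <- fams
  sequences <- vapply(genes$protein_id, function(p) {
    s <- strsplit(fam_seq[[family_of[[p]]]], "")[[1L]]
    mut <- stats::runif(length(s)) < 0.05
    s[mut] <- sample(aa, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))

  collection <- new_genome_collection(
    genes, stats::setNames(nchar(sequences), names(sequences)))

  hits <- .synth_hits(genes, family_of, fam_len, cfg)

  go <- .synth_go(fams, pos_fams, as.vector(nbr_fams), family_of,
                  genes$protein_id, cfg)

  pos_proteins <- genes$protein_id[family_of[genes$protein_id] %in% pos_fams]
  neg_pool <- genes$protein_id[family_of[genes$protein_id] %in% free_fams]
  n_neg <- min(cfg$n_negative_instances, length(neg_pool))
  neg_proteins <- sort(sample(neg_pool, n_neg))
  labels <- c(stats::setNames(rep("T", length(pos_proteins)), pos_proteins),
              stats::setNames(rep("F", length(neg_proteins)), neg_proteins))

  planted <- do.call(rbind, lapply(seq_len(n_pos), function(p)
    data.frame(query_family = pos_fams[p], neighbor_family = nbr_fams[p, ],
               stringsAsFactors = FALSE)))

  list(collection = collection, sequences = sequences, hits = hits,
       annotations = go$annotations, dag = go$dag, photo_terms = go$photo_terms,
       labels = labels,
       ground_truth = list(family_of = family_of, positive_families = pos_fams,
                           neighbor_families = nbr_fams, planted = planted,
                           fires = fires, decoy_blocks = decoy_blocks),
       config = cfg)
}

# similarity table: strong within-family hits (one E-value per unordered
# pair, emitted in both directions), sparse weak between-family noise
.synth_hits <- function(genes, family_of, fam_len, cfg) {
  by_fam <- split(genes$protein_id, family_of[genes$protein_id])
  rows <- list()
  for (fam in names(by_fam)) {
    members <- sort(by_fam[[fam]])
    if (length(members) < 2L) next
    prs <- utils::combn(members, 2L)
    npair <- ncol(prs)
    ev <- 10^stats::runif(npair, cfg$evalue_within[1L], cfg$evalue_within[2L])
    bit <- stats::runif(npair, 150, 400)
    pid <- stats::runif(npair, 70, 99)
    alen <- as.integer(round(0.9 * fam_len[[fam]]))
    rows[[fam]] <- data.frame(
      query_id = c(prs[1L, ], prs[2L, ]), subject_id = c(prs[2L, ], prs[1L, ]),
      percent_identity = rep(pid, 2L), alignment_length = alen,
      evalue = rep(ev, 2L), bitscore = rep(round(bit, 1), 2L),
      stringsAsFactors = FALSE)
  }
  n_noise <- as.integer(round(cfg$between_hit_prob * nrow(genes) * 10))
  if (n_noise > 0L) {
    qa <- sample(genes$protein_id, n_noise, replace = TRUE)
    qb <- sample(genes$protein_id, n_noise, replace = TRUE)
    keep <- family_of[qa] != family_of[qb]
    if (any(keep)) {
      qa <- qa[keep]; qb <- qb[keep]
      rows[["noise"]] <- data.frame(
        query_id = qa, subject_id = qb,
        percent_identity = round(stats::runif(sum(keep), 20, 35), 1),
        alignment_length = as.integer(round(0.3 * fam_len[family_of[qa]])),
        evalue = 10^stats::runif(sum(keep), cfg$evalue_between[1L], cfg$evalue_between[2L]),
        bitscore = round(stats::runif(sum(keep), 30, 60), 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$query_coverage <- round(100 * out$alignment_length /
                                as.numeric(fam_len[family_of[out$query_id]]), 1)
  out
}

# small synthetic GO: photosynthesis branch at depth 3 plus non-photo
# branches of depth >= 3; annotations per protein with noise.  Planted
# neighbor families are functionally coupled to their queries, so they draw
# from the photosynthesis subtree as well.
.synth_go <- function(fams, pos_fams, nbr_fams, family_of, proteins, cfg) {
  photo_leaves <- c("GO:0009765", "GO:0019684", "GO:0009773")
  neg_parents <- c("GO:0006259", "GO:0006412", "GO:0055085")
  neg_leaves <- c("GO:0006260", "GO:0006261", "GO:0006413", "GO:0006414",
                  "GO:0055076", "GO:0055072")
  edges <- rbind(
    data.frame(child = "GO:0008152", parent = "GO:0008150"),
    data.frame(child = "GO:0006091", parent = "GO:0008152"),
    data.frame(child = "GO:0015979", parent = "GO:0006091"),
    data.frame(child = photo_leaves, parent = "GO:0015979"),
    data.frame(child = "GO:0009987", parent = "GO:0008150"),
    data.frame(child = "GO:0044237", parent = "GO:0009987"),
    data.frame(child = neg_parents, parent = "GO:0044237"),
    data.frame(child = neg_leaves,
               parent = rep(neg_parents, times = c(2L, 2L, 2L))))
  dag <- new_go_dag(edges)
  pool <- c(photo_leaves, "GO:0015979", neg_leaves, neg_parents)
  fam_term <- stats::setNames(
    ifelse(fams %in% c(pos_fams, nbr_fams),
           sample(c(photo_leaves, "GO:0015979"), length(fams), replace = TRUE),
           sample(neg_leaves, length(fams), replace = TRUE)),
    fams)
  annotations <- lapply(stats::setNames(proteins, proteins), function(p) {
    t0 <- fam_term[[family_of[[p]]]]
    if (stats::runif(1) < cfg$go_noise) t0 <- sample(pool, 1L)
    unique(c(t0, if (stats::runif(1) < 0.3) sample(pool, 1L)))
  })
  list(dag = dag, annotations = annotations,
       photo_terms = c("GO:0015979", photo_leaves))
}

#' Write a generated collection to disk in standard formats
#'
#' Emits exactly what [read_genome_collection()] and
#' [read_similarity_table()] consume: per-genome GFF3, one protein FASTA,
#' a 12-column similarity TSV, a GO annotation TSV, an OBO ontology and a
#' label TSV.
#'
#' @param gen output of [generate_collection()].
#' @param dir output directory.
#' @return invisibly, a named list of the written paths.
#' @export
write_collection <- function(gen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gff_dir <- file.path(dir, "gff")
  paths <- list(gff = write_genome_gff3(gen$collection, gff_dir),
                fasta = file.path(dir, "proteins.faa"),
                hits = file.path(dir, "hits.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                obo = file.path(dir, "ontology.obo"),
                labels = file.path(dir, "labels.tsv"))
  write_protein_fasta(gen$sequences, paths$fasta)
  write_similarity_table(gen$hits, paths$hits)
  ann <- data.frame(protein_id = rep(names(gen$annotations),
                                     lengths(gen$annotations)),
                    go_id = unlist(gen$annotations, use.names = FALSE))
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_obo(gen$dag, paths$obo)
  utils::write.table(data.frame(protein_id = names(gen$labels),
                                label = unname(gen$labels)),
                     paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a GO DAG as a minimal OBO file
#' @param dag `go_dag`.
#' @param path output file.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in sort(dag$terms)) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Regenerate the four-genome demonstration collection
#'
#' A hard-coded toy of four genomes whose query proteins share one family at
#' the loose stringency and split apart as the E-value cutoff tightens:
#' at 1e-50 the neighbor family c1 splits so that its surviving part is seen
#' in only two genomes (unscored) while the split-off part (c4) remains
#' conserved in three; at 1e-100 the query of genome 1 becomes a singleton
#' family and loses all its scores.  Filler families shared by varying
#' genome subsets make the genome distance matrix non-degenerate.
#'
#' @return list like [generate_collection()] (without GO annotations) plus
#'   `toy_families` naming the intended family memberships.
#' @export
regenerate_fig1_toy <- function() {
  genomes <- paste0("G", 1:4)
  qs <- paste0("q", 1:4)
  as_ <- c("a1", "a2", "a2b", "a3", "a4")
  bs <- paste0("b", 1:4)
  ds <- paste0("d", 1:4)
  filler_sets <- list(f01 = 1:4, f02 = 1:4, f03 = 1:4, f04 = 1:4, f05 = 1:4,
                      f06 = 1:4, f07 = c(1, 2), f08 = c(1, 3), f09 = c(1, 4),
                      f10 = c(2, 3), f11 = c(2, 4), f12 = c(3, 4))
  genes <- list()
  add_gene <- function(gid, pid, start, len = 300L, strand = "+") {
    data.frame(gene_id = paste0("gene_", pid), genome_id = gid,
               contig_id = paste0(gid, "_c1"), start = start,
               end = start + len - 1L, strand = strand, protein_id = pid,
               stringsAsFactors = FALSE)
  }
  for (i in 1:4) {
    gid <- genomes[i]
    cluster <- c(qs[i], paste0("a", i), if (i == 2) "a2b", bs[i], ds[i])
    pos <- 1L
    for (p in cluster) {
      genes[[length(genes) + 1L]] <- add_gene(gid, p, pos)
      pos <- pos + 300L + 100L          # 100-bp gaps, same strand
    }
    pos <- pos + 2000L
    for (f in names(filler_sets)) {
      if (i %in% filler_sets[[f]]) {
        genes[[length(genes) + 1L]] <- add_gene(gid, paste0(f, "_", gid), pos)
        pos <- pos + 300L + 2000L
      }
    }
  }
  genes <- do.call(rbind, genes)
  sequences <- stats::setNames(
    vapply(seq_len(nrow(genes)), function(i)
      paste(rep("M", 100L), collapse = ""), character(1)),
    genes$protein_id)
  collection <- new_genome_collection(
    genes, stats::setNames(rep(100L, nrow(genes)), genes$protein_id))

  pair_hits <- function(ids, evalue, bitscore) {
    if (length(ids) < 2L) return(NULL)
    prs <- utils::combn(sort(ids), 2L)
    data.frame(query_id = c(prs[1L, ], prs[2L, ]),
               subject_id = c(prs[2L, ], prs[1L, ]),
               percent_identity = 90, alignment_length = 95L,
               evalue = evalue, bitscore = bitscore,
               query_coverage = 95, stringsAsFactors = FALSE)
  }
  cross_hits <- function(a, b, evalue, bitscore) {
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    data.frame(query_id = c(grid$a, grid$b), subject_id = c(grid$b, grid$a),
               percent_identity = 45, alignment_length = 60L,
               evalue = evalue, bitscore = bitscore,
               query_coverage = 60, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    pair_hits(qs[2:4], 1e-150, 320),
    cross_hits("q1", qs[2:4], 1e-60, 200),
    pair_hits(c("a1", "a2"), 1e-120, 300),
    pair_hits(c("a2b", "a3", "a4"), 1e-120, 300),
    cross_hits(c("a1", "a2"), c("a2b", "a3", "a4"), 1e-30, 90),
    pair_hits(bs, 1e-160, 340),
    pair_hits(ds, 1e-160, 340),
    do.call(rbind, lapply(names(filler_sets), function(f)
      pair_hits(paste0(f, "_", genomes[filler_sets[[f]]]), 1e-150, 310))))
  rownames(hits) <- NULL
  labels <- stats::setNames(rep("T", 4L), qs)
  list(collection = collection, sequences = sequences, hits = hits,
       labels = labels,
       toy_families = list(query = qs, c1_at_1e50 = c("a1", "a2"),
                           c4_at_1e50 = c("a2b", "a3", "a4"),
                           c2 = bs, c3 = ds))
}
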