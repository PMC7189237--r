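#' Read a genome collection from GFF3 annotations and protein FASTA files
#'
#' Builds the internal genome model used by all downstream steps: one row per
#' protein-coding gene, cross-referenced against the supplied proteomes.
#' Coordinates are 1-based inclusive as in GFF3.
#'
#' @param gff_paths character vector of GFF3 files, one per genome.  The
#'   genome id is taken from the file name (without extension) unless the file
#'   carries a `##genome-id` pragma.
#' @param fasta_paths character vector of protein FASTA files.  Record ids (up
#'   to the first whitespace) must match the `protein_id` attribute (falling
#'   back to `ID`) of the gene/CDS features.
#' @param feature_types GFF3 feature types treated as protein-coding genes.
#' @return An object of class `genome_collection`: a list with elements
#'   `genes` (data.frame: gene_id, genome_id, contig_id, start, end, strand,
#'   protein_id, sorted by genome, contig, start), `protein_lengths` (named
#'   integer vector over all proteins) and `genome_ids`.
#' @details Every gene must have a protein sequence; a missing sequence, a
#'   malformed GFF3 line or a protein id duplicated across genomes is an
#'   error.  Neighborhood calling never spans contigs, so contig identity is
#'   kept per gene.
#' @export
read_genome_collection <- function(gff_paths, fasta_paths,
                                   feature_types = c("gene", "CDS")) {
  stopifnot(length(gff_paths) >= 1L, length(fasta_paths) >= 1L)
  seqs <- do.call(c, lapply(fasta_paths, Biostrings::readAAStringSet))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids in FASTA input: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  protein_lengths <- stats::setNames(Biostrings::width(seqs), names(seqs))

  gene_tabs <- lapply(gff_paths, function(path) {
    .validate_gff3_lines(path)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% feature_types]
    if (length(gr) == 0L)
      stop("no gene/CDS features in ", path)
    meta <- S4Vectors::mcols(gr)
    pid <- if ("protein_id" %in% colnames(meta)) as.character(meta$protein_id) else rep(NA_character_, length(gr))
    id <- if ("ID" %in% colnames(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
    pid <- ifelse(is.na(pid), id, pid)
    if (anyNA(pid))
      stop("feature without ID/protein_id attribute in ", path)
    genome_id <- .gff3_genome_id(path)
    data.frame(
      gene_id = ifelse(is.na(id), pid, id),
      genome_id = genome_id,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      protein_id = pid,
      stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_tabs)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene with undefined strand: ",
         genes$gene_id[!genes$strand %in% c("+", "-")][1L])
  missing <- setdiff(genes$protein_id, names(protein_lengths))
  if (length(missing))
    stop("no protein sequence for gene(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  if (anyDuplicated(genes$protein_id))
    stop("protein_id duplicated across genes: ",
         paste(unique(genes$protein_id[duplicated(genes$protein_id)]), collapse = ", "))
  new_genome_collection(genes, protein_lengths)
}

#' Construct a genome collection from in-memory tables
#'
#' Lower-level constructor used by the synthetic generator and by tests.
#'
#' @param genes data.frame with columns gene_id, genome_id, contig_id, start,
#'   end, strand, protein_id.
#' @param protein_lengths named integer vector covering every protein_id.
#' @return `genome_collection` object.
#' @export
new_genome_collection <- function(genes, protein_lengths) {
  req <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand", "protein_id")
  stopifnot(all(req %in% names(genes)))
  if (any(genes$start < 1L) || any(genes$end < genes$start))
    stop("invalid gene coordinates (need 1 <= start <= end)")
  # total order: contig, start, end, gene_id (determinism under coordinate ties)
  o <- order(genes$genome_id, genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, req, drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 protein_lengths = protein_lengths,
                 genome_ids = unique(genes$genome_id)),
            class = "genome_collection")
}

#' @export
print.genome_collection <- function(x, ...) {
  cat("Genome collection:", length(x$genome_ids), "genome(s),",
      nrow(x$genes), "protein-coding genes\n")
  sizes <- proteome_sizes(x)
  cat("  proteome sizes:", paste(paste0(names(sizes), "=", sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Proteome sizes of a collection
#' @param collection `genome_collection`.
#' @return named integer vector, protein-coding gene count per genome.
#' @export
proteome_sizes <- function(collection) {
  tab <- table(collection$genes$genome_id)
  stats::setNames(as.integer(tab), names(tab))[collection$genome_ids]
}

#' Genes of one genome, in coordinate order
#' @param collection `genome_collection`.
#' @param genome_id genome to extract.
#' @return data.frame of genes sorted by (contig_id, start).
#' @export
genome_genes <- function(collection, genome_id) {
  g <- collection$genes[collection$genes$genome_id == genome_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown genome: ", genome_id)
  rownames(g) <- NULL
  g
}

#' Write the genome model back to GFF3 (one file per genome)
#'
#' @param collection `genome_collection`.
#' @param dir output directory; files are named `<genome_id>.gff3`.
#' @return invisibly, the written paths.
#' @export
write_genome_gff3 <- function(collection, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(collection$genome_ids, function(gid) {
    g <- genome_genes(collection, gid)
    path <- file.path(dir, paste0(gid, ".gff3"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##gff-version 3", paste0("##genome-id ", gid)), con)
    writeLines(sprintf("%s\tphotognn\tgene\t%d\t%d\t.\t%s\t.\tID=%s;protein_id=%s",
                       g$contig_id, g$start, g$end, g$strand, g$gene_id, g$protein_id),
               con)
    path
  }, character(1))
  invisible(paths)
}

#' Write protein sequences of a collection to FASTA
#' @param sequences named character vector (or AAStringSet) of protein
#'   sequences.
#' @param path output file.
#' @export
write_protein_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

# 9 tab-separated fields on every non-comment line; report the first offender
.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GFF3 line ", bad, " in ", path, " (", nf[which(nf != 9L)[1L]],
         " fields, expected 9)")
  }
  invisible(TRUE)
}

.gff3_genome_id <- function(path) {
  first <- readLines(path, n = 20L, warn = FALSE)
  pragma <- grep("^##genome-id ", first, value = TRUE)
  if (length(pragma)) sub("^##genome-id\\s+", "", pragma[1L])
  else sub("\\.(gff3?|gff)$", "", basename(path), ignore.case = TRUE)
}

#' Read an all-vs-all protein similarity table (BLAST tabular, 12 columns)
#'
#' Parses the standard `outfmt 6` dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore).  Rows whose
#' query or subject is unknown to the collection are dropped with a warning
#' giving the count.  Query coverage is derived as alignment length over
#' query sequence length (the tabular format carries no coverage column).
#'
#' @param path tab-separated file.
#' @param collection optional `genome_collection`; if given, ids are checked
#'   against it and query coverage is computed from its protein lengths.
#' @return data.frame of hits with columns query_id, subject_id,
#'   percent_identity, alignment_length, evalue, bitscore, query_coverage
#'   (NA when no collection is supplied).
#' @export
read_similarity_table <- function(path, collection = NULL) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character", fill = FALSE,
                           col.names = cols)
  if (nrow(raw) == 0L) return(.empty_hits())
  ev <- suppressWarnings(as.numeric(raw$evalue))
  if (anyNA(ev))
    stop("non-numeric E-value at row ", which(is.na(ev))[1L], " of ", path)
  hits <- data.frame(query_id = raw$query_id,
                     subject_id = raw$subject_id,
                     percent_identity = as.numeric(raw$percent_identity),
                     alignment_length = as.integer(raw$alignment_length),
                     evalue = ev,
                     bitscore = as.numeric(raw$bitscore),
                     query_coverage = NA_real_,
                     stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) stop("negative E-value in ", path)
  if (!is.null(collection)) {
    known <- names(collection$protein_lengths)
    keep <- hits$query_id %in% known & hits$subject_id %in% known
    if (any(!keep)) {
      warning(sum(!keep), " similarity rows referencing unknown protein ids dropped")
      hits <- hits[keep, , drop = FALSE]
      rownames(hits) <- NULL
    }
    hits$query_coverage <-
      100 * hits$alignment_length / as.numeric(collection$protein_lengths[hits$query_id])
  }
  hits
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             evalue = numeric(), bitscore = numeric(),
             query_coverage = numeric(), stringsAsFactors = FALSE)
}

#' Write a similarity table in BLAST 12-column tabular format
#' @param hits data.frame as returned by [read_similarity_table()].
#' @param path output file.
#' @export
write_similarity_table <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id,
                    formatC(hits$percent_identity, format = "f", digits = 1),
                    hits$alignment_length, 0L, 0L, 1L, hits$alignment_length,
                    1L, hits$alignment_length,
                    format(hits$evalue, scientific = TRUE, digits = 3),
                    hits$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
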