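# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Read a Gene Ontology DAG from an OBO file
#'
#' Minimal OBO reader covering what ancestor traversal needs: `[Term]`
#' stanzas with `id`, `name`, `namespace` and `is_a` fields; obsolete terms
#' are skipped.  Only `is_a` edges are retained.
#'
#' @param path OBO file.
#' @return `go_dag`: list with `terms` (character vector), `parents` (named
#'   list of is_a parents per term), `namespace` (named character).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  terms <- character(); parents <- list(); nspace <- character()
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    block <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get_field <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub(" !.*$", "", sub(paste0("^", key, ": "), "", v))
    }
    if (length(get_field("is_obsolete")) && get_field("is_obsolete")[1L] == "true") next
    id <- get_field("id")[1L]
    if (is.na(id)) next
    terms <- c(terms, id)
    parents[[id]] <- trimws(get_field("is_a"))
    ns <- get_field("namespace")
    nspace[id] <- if (length(ns)) ns[1L] else NA_character_
  }
  structure(list(terms = terms, parents = parents, namespace = nspace),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges\n")
  invisible(x)
}

#' Construct a GO DAG from an edge list (for synthetic ontologies)
#' @param edges data.frame with columns `child`, `parent` (is_a edges).
#' @param terms optional extra (root) term ids.
#' @param namespace optional named namespace vector.
#' @return `go_dag`.
#' @export
new_go_dag <- function(edges, terms = NULL, namespace = NULL) {
  all_terms <- unique(c(edges$child, edges$parent, terms))
  parents <- lapply(stats::setNames(all_terms, all_terms),
                    function(t) edges$parent[edges$child == t])
  if (is.null(namespace))
    namespace <- stats::setNames(rep(NA_character_, length(all_terms)), all_terms)
  structure(list(terms = all_terms, parents = parents, namespace = namespace),
            class = "go_dag")
}

#' Ancestor closure of a GO term set
#'
#' The input terms together with every term reachable by `is_a` edges up to
#' the root(s).
#'
#' @param terms character vector of GO ids.
#' @param dag `go_dag`.
#' @return character vector (sorted, unique).
#' @export
ancestor_closure <- function(terms, dag) {
  unknown <- setdiff(terms, dag$terms)
  if (length(unknown)) stop("unknown GO term(s): ", paste(unknown, collapse = ", "))
  seen <- character(); frontier <- unique(terms)
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  sort(unique(seen))
}

#' Depth of GO terms (shortest is_a path to the namespace root)
#'
#' The root of a namespace (a term without parents) has depth 0; every other
#' term's depth is the length of its shortest chain of `is_a` edges to a
#' root.  Under this convention photosynthesis (GO:0015979) sits at level 3
#' of the biological-process ontology.
#'
#' @param terms character vector of GO ids.
#' @param dag `go_dag`.
#' @return named integer vector of depths.
#' @export
go_depth <- function(terms, dag) {
  vapply(stats::setNames(terms, terms), function(t) {
    if (!t %in% dag$terms) stop("unknown GO term: ", t)
    depth <- 0L; frontier <- t
    repeat {
      if (any(lengths(dag$parents[frontier]) == 0L)) return(depth)
      frontier <- unique(unlist(dag$parents[frontier]))
      depth <- depth + 1L
    }
  }, integer(1))
}

#' Transfer positive (photosynthetic) labels by stringent similarity
#'
#' A collection protein receives the positive label when some similarity hit
#' connecting it to a reference positive protein has percent identity and
#' percent query coverage both strictly above the thresholds.
#'
#' @param reference_positive_ids ids of reference proteins with confirmed
#'   function.
#' @param hits similarity data.frame with `query_coverage` populated.
#' @param min_identity,min_coverage strict lower bounds (default 80).
#' @return character vector of labeled collection protein ids.
#' @export
transfer_positive_labels <- function(reference_positive_ids, hits,
                                     min_identity = 80, min_coverage = 80) {
  ok <- hits$percent_identity > min_identity &
    !is.na(hits$query_coverage) & hits$query_coverage > min_coverage
  h <- hits[ok, , drop = FALSE]
  from_ref <- h$query_id %in% reference_positive_ids
  to_ref <- h$subject_id %in% reference_positive_ids
  sort(unique(c(h$subject_id[from_ref], h$query_id[to_ref])))
}

#' Select negative (non-photosynthetic) candidates
#'
#' A candidate is kept when (a) the ancestor closure of its GO annotations
#' contains no photosynthesis-related term, and (b) at least one annotated
#' term is at least `min_level` deep — shallow annotations are too vague to
#' certify the absence of a function annotated at level 3.
#'
#' @param candidates protein ids to screen.
#' @param annotations named list: protein id -> GO term character vector.
#' @param dag `go_dag`.
#' @param photo_terms photosynthesis-related GO ids (see
#'   [load_photo_go_terms()]).
#' @param min_level minimum annotation depth (default 3).
#' @return character vector of retained protein ids.
#' @export
select_negatives <- function(candidates, annotations, dag, photo_terms,
                             min_level = 3L) {
  stopifnot(length(photo_terms) > 0L)
  keep <- vapply(candidates, function(p) {
    terms <- annotations[[p]]
    if (is.null(terms) || length(terms) == 0L) return(FALSE)
    closure <- ancestor_closure(terms, dag)
    if (length(intersect(closure, photo_terms))) return(FALSE)
    any(go_depth(terms, dag) >= min_level)
  }, logical(1))
  candidates[keep]
}

#' Load the photosynthesis GO-term list
#'
#' Reads a plain-text list of GO ids (one per line, `#` comments allowed).
#' The packaged default is a curated list of well-known photosynthesis terms
#' anchored at GO:0015979; users reproducing a specific study should
#' substitute their own list.
#'
#' @param path file of GO ids; default the packaged list.
#' @return character vector of GO ids.
#' @export
load_photo_go_terms <- function(path = system.file("extdata", "photo_go_terms.txt",
                                                   package = "photognn")) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sub("\\s.*$", "", lines)
}

#' Balanced random sample from the negative pool
#'
#' Uniform sample without replacement, reproducible by seed; the caller's
#' RNG state is untouched.
#'
#' @param pool candidate protein ids.
#' @param n_target sample size (<= pool size).
#' @param seed integer seed.
#' @return character vector of sampled ids.
#' @export
balance_sample <- function(pool, n_target, seed) {
  if (n_target > length(pool))
    stop("negative pool (", length(pool), ") smaller than target ", n_target)
  if (n_target == 0L) return(character(0))
  .with_seed(seed, sample(pool, n_target))
}
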