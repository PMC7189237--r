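# md5 fingerprint of an arbitrary R object (for cache keys / manifest)
.md5_of <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(obj, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full genome-neighborhood classification protocol
#'
#' Orchestrates ingest, neighborhood calling, family clustering at each
#' E-value stringency, genome distances, Phylo scoring, profile assembly,
#' discretization, deduplication, export and (optionally) nested
#' cross-validation, writing a manifest that makes the run reproducible.
#' Each stage's output is cached under `out_dir/cache`; deleting a cache
#' file recomputes only that stage and its dependents.
#'
#' @param input either the list returned by [generate_collection()] /
#'   [regenerate_fig1_toy()], or a list of paths with elements `gff`
#'   (vector), `fasta` (vector), `hits` (file) and optionally `labels`
#'   (TSV protein_id/label).
#' @param out_dir artifact directory (created if needed).
#' @param thresholds E-value cutoffs (default `c(1e-10, 1e-50, 1e-100)`).
#' @param seed integer seed for fold construction and balancing.
#' @param classifier passed to [nested_cv()].
#' @param cv run nested cross-validation (default TRUE).
#' @param outer,inner,select_k,pca,balance passed to [nested_cv()].
#' @param force recompute all stages ignoring the cache.
#' @return list with `profile`, `discretized`, `deduplicated`, `cv` (or
#'   NULL), `paths` and `manifest`.
#' @export
run_pipeline <- function(input, out_dir, thresholds = c(1e-10, 1e-50, 1e-100),
                         seed = 1L, classifier = "rf", cv = TRUE,
                         outer = 10L, inner = 2L, select_k = NULL, pca = NULL,
                         balance = "none", force = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  if (!dir.exists(cache_dir)) dir.create(cache_dir)
  manifest <- list(seed = seed, thresholds = thresholds,
                   r_version = as.character(getRversion()), stages = list())
  stage <- function(name, key_obj, fun) {
    path <- file.path(cache_dir, paste0(name, ".rds"))
    key <- .md5_of(key_obj)
    if (!force && file.exists(path)) {
      cached <- readRDS(path)
      if (identical(cached$key, key)) {
        manifest$stages[[name]] <<- c(cached$info, cached = TRUE)
        return(cached$value)
      }
    }
    t0 <- proc.time()[["elapsed"]]
    value <- fun()
    info <- list(key = key, elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
                 size = if (is.data.frame(value)) nrow(value)
                        else if (is.matrix(value)) paste(dim(value), collapse = "x")
                        else length(value))
    saveRDS(list(key = key, value = value, info = info), path, version = 2)
    manifest$stages[[name]] <<- c(info, cached = FALSE)
    value
  }

  if (!is.null(input$collection)) {
    collection <- input$collection
    hits <- input$hits
    labels <- input$labels
  } else {
    collection <- read_genome_collection(input$gff, input$fasta)
    hits <- read_similarity_table(input$hits, collection)
    labels <- NULL
    if (!is.null(input$labels)) {
      lt <- utils::read.table(input$labels, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      labels <- stats::setNames(lt$label, lt$protein_id)
    }
  }
  input_key <- list(.md5_of(collection$genes), .md5_of(hits), thresholds)

  clusters <- stage("neighborhoods", input_key,
                    function() call_neighborhoods(collection))
  partitions <- stage("families", input_key,
                      function() cluster_families(hits, collection, thresholds))
  dm <- stage("distances", input_key,
              function() genome_distance_matrix(hits, collection))
  scored <- stage("scores", list(input_key, .md5_of(clusters)), function() {
    lapply(partitions, function(p)
      score_adjacencies(adjacency_evidence(clusters, p), dm))
  })
  queries <- if (!is.null(labels)) names(labels) else
    unique(collection$genes$protein_id)
  profile <- stage("profile", list(input_key, queries), function()
    build_profile(queries, partitions, scored, labels = labels))
  disc <- stage("discretize", list(input_key, queries), function() {
    cut <- tryCatch(fit_quartile_cutpoints(profile),
                    error = function(e) reference_cutpoints)
    discretize_profile(profile, cut)
  })
  dedup <- deduplicate_profile(disc)
  paths <- list(arff = file.path(out_dir, "profile.arff"),
                csv = file.path(out_dir, "profile.csv"),
                clusters = file.path(out_dir, "neighborhoods.tsv"),
                distances = file.path(out_dir, "distances.tsv"),
                manifest = file.path(out_dir, "manifest.json"),
                metrics = file.path(out_dir, "metrics.json"))
  utils::write.table(clusters, paths$clusters, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(genome_id = rownames(dm), dm,
                                check.names = FALSE),
                     paths$distances, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(dedup$x) > 0L && any(dedup$labels %in% c("T", "F"))) {
    write_arff(dedup, paths$arff)
    write_profile_csv(dedup, paths$csv)
  }
  cv_res <- NULL
  if (cv && sum(profile$labels == "T") >= outer &&
      sum(profile$labels == "F") >= outer) {
    cv_res <- stage("cv", list(input_key, classifier, outer, inner, seed,
                               select_k, pca, balance), function()
      nested_cv(profile, classifier = classifier, outer = outer,
                inner = inner, select_k = select_k, pca = pca,
                balance = balance, seed = seed))
    jsonlite::write_json(list(classifier = classifier,
                              mean = as.list(cv_res$mean),
                              sd = as.list(cv_res$sd)),
                         paths$metrics, auto_unbox = TRUE, digits = NA)
  }
  manifest$instances <- nrow(dedup$x)
  manifest$features <- ncol(dedup$x)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  list(profile = profile, discretized = disc, deduplicated = dedup,
       cv = cv_res, paths = paths, manifest = manifest)
}
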