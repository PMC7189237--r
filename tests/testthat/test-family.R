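test_that("the similarity network keeps only hits passing the threshold", {
  hits <- make_hits(list(q = "a", s = "b", e = 1e-60, bit = 100),
                    list(q = "b", s = "a", e = 1e-80, bit = 150),
                    list(q = "a", s = "c", e = 1e-20, bit = 90),
                    list(q = "a", s = "a", e = 0, bit = 500))
  g <- build_ssn(hits, 1e-50)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_false(igraph::are_adjacent(g, "a", "c"))
  expect_equal(igraph::E(g, P = c("a", "b"))$weight, 150)  # max over both directions
  expect_equal(sum(igraph::which_loop(g)), 0L)
  # stricter threshold never adds edges
  g10 <- build_ssn(hits, 1e-10)
  expect_gte(igraph::ecount(g10), igraph::ecount(g))
})

test_that("MCL recovers components and matches a brute-force oracle", {
  # two disjoint triangles -> exactly the two components
  edges <- data.frame(a = c("a1", "a2", "a3", "b1", "b2", "b3"),
                      b = c("a2", "a3", "a1", "b2", "b3", "b1"),
                      weight = 1)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  part <- mcl_cluster(g)
  expect_equal(length(part$families), 2L)
  expect_setequal(part$families[[1L]], c("a1", "a2", "a3"))

  # isolated vertex -> singleton family
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "solo"
  expect_equal(length(mcl_cluster(g1)$families), 1L)

  # barbell: two 4-cliques joined by one weak edge split into the cliques
  cl <- expand.grid(a = paste0("x", 1:4), b = paste0("x", 1:4),
                    stringsAsFactors = FALSE)
  cl <- cl[cl$a < cl$b, ]
  cr <- cl; cr$a <- sub("x", "y", cr$a); cr$b <- sub("x", "y", cr$b)
  edges <- rbind(cbind(cl, weight = 10), cbind(cr, weight = 10),
                 data.frame(a = "x4", b = "y1", weight = 0.1))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  part <- mcl_cluster(g, inflation = 2)
  expect_equal(length(part$families), 2L)
  expect_setequal(part$families[[which(vapply(part$families, function(f) "x1" %in% f, TRUE))]],
                  paste0("x", 1:4))

  # random <=10-node graphs agree with the independent dense-matrix oracle
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    adj <- matrix(0, n, n)
    m <- sample(3:(n * 2), 1)
    for (k in seq_len(m)) {
      ij <- sample(n, 2)
      w <- round(stats::runif(1, 0.5, 5), 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- w
    }
    nodes <- sprintf("v%02d", seq_len(n))
    dimnames(adj) <- list(nodes, nodes)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    part <- mcl_cluster(g)
    mine <- as.integer(factor(part$family_of[nodes]))
    oracle <- oracle_mcl(adj)
    expect_true(same_partition(mine, oracle))
    # refinement of connected components
    comp <- igraph::components(g)$membership[nodes]
    for (fam in part$families)
      expect_equal(length(unique(comp[fam])), 1L)
  }
})

test_that("family count is non-decreasing in E-value stringency", {
  gen <- generate_collection(synth_config(n_genomes = 5L, n_families = 40L,
                                          n_positive_families = 5L,
                                          n_negative_instances = 10L, seed = 7L))
  parts <- cluster_families(gen$hits, gen$collection)
  counts <- vapply(parts, function(p) length(p$families), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("reciprocal best hits require mutual best and break ties canonically", {
  coll <- new_genome_collection(
    rbind(make_genes(list(c(1, 300, "+"), c(1000, 1300, "+")), genome_id = "gA"),
          make_genes(list(c(1, 300, "+"), c(1000, 1300, "+")), genome_id = "gB")),
    c(gA_p01 = 100L, gA_p02 = 100L, gB_p01 = 100L, gB_p02 = 100L))
  # mutual best pair
  hits <- make_hits(list(q = "gA_p01", s = "gB_p01", e = 1e-80, bit = 300),
                    list(q = "gB_p01", s = "gA_p01", e = 1e-80, bit = 300))
  expect_equal(reciprocal_best_hits(hits, coll, "gA", "gB")$protein_b, "gB_p01")

  # p's best is q but q prefers p' -> excluded
  hits <- make_hits(list(q = "gA_p01", s = "gB_p01", e = 1e-80, bit = 300),
                    list(q = "gB_p01", s = "gA_p02", e = 1e-90, bit = 400),
                    list(q = "gB_p01", s = "gA_p01", e = 1e-80, bit = 300))
  expect_equal(nrow(reciprocal_best_hits(hits, coll, "gA", "gB")), 0L)

  # bitscore tie resolved by lower evalue then lexicographic subject,
  # independent of row order: enumerate all hit-order permutations
  base <- make_hits(list(q = "gA_p01", s = "gB_p02", e = 1e-50, bit = 300),
                    list(q = "gA_p01", s = "gB_p01", e = 1e-50, bit = 300),
                    list(q = "gB_p01", s = "gA_p01", e = 1e-60, bit = 300))
  for (perm in list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    rbh <- reciprocal_best_hits(base[perm, ], coll, "gA", "gB")
    # equal evalue: gB_p01 wins lexicographically and is reciprocal
    expect_equal(rbh$protein_b, "gB_p01")
  }
  # RBH count bounded by the smaller proteome
  gen <- generate_collection(synth_config(n_genomes = 3L, n_families = 30L,
                                          n_positive_families = 4L,
                                          n_negative_instances = 5L, seed = 2L))
  sizes <- proteome_sizes(gen$collection)
  rbh <- reciprocal_best_hits(gen$hits, gen$collection, "g01", "g02")
  expect_lte(nrow(rbh), min(sizes[c("g01", "g02")]))
})
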