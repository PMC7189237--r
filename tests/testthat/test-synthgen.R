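small_cfg <- function(n_genomes = 5L, ...) {
  synth_config(n_genomes = n_genomes, n_families = 40L,
               n_positive_families = 5L, n_negative_instances = 20L, ...)
}

test_that("generation is deterministic and internally consistent", {
  g1 <- generate_collection(small_cfg(seed = 21L))
  g2 <- generate_collection(small_cfg(seed = 21L))
  expect_identical(g1$collection$genes, g2$collection$genes)
  expect_identical(g1$hits, g2$hits)
  expect_identical(g1$sequences, g2$sequences)
  # written artifacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_collection(g1, d1); p2 <- write_collection(g2, d2)
  expect_identical(unname(tools::md5sum(p1$hits)), unname(tools::md5sum(p2$hits)))
  expect_identical(readLines(p1$gff[1L]), readLines(p2$gff[1L]))
  # every gene has a sequence of consistent length
  expect_setequal(names(g1$sequences), g1$collection$genes$protein_id)
  expect_equal(unname(nchar(g1$sequences)),
               unname(g1$collection$protein_lengths[names(g1$sequences)]))
  # infeasible layout rejected
  expect_error(synth_config(n_families = 5L, n_positive_families = 5L,
                            cluster_size = 4L), "planted clusters")
})

test_that("similarity network plus MCL recovers the planted families exactly", {
  gen <- generate_collection(small_cfg(seed = 13L))
  part <- cluster_families(gen$hits, gen$collection, 1e-10)[[1L]]
  truth <- gen$ground_truth$family_of[names(part$family_of)]
  tab <- table(part$family_of, truth)
  expect_true(all(rowSums(tab > 0) == 1))   # no family mixes planted groups
  expect_true(all(colSums(tab > 0) == 1))   # no planted group is split
})

test_that("full conservation scores every planted adjacency; none survives at zero", {
  score_planted <- function(prob, seed) {
    gen <- generate_collection(small_cfg(n_genomes = 10L,
                                         conservation_prob = prob, seed = seed))
    part <- cluster_families(gen$hits, gen$collection, 1e-10)[[1L]]
    cl <- call_neighborhoods(gen$collection)
    dm <- genome_distance_matrix(gen$hits, gen$collection)
    sc <- score_adjacencies(adjacency_evidence(cl, part), dm)
    fam_label <- function(fam) {   # map planted family name -> detected id
      member <- names(gen$ground_truth$family_of)[gen$ground_truth$family_of == fam][1L]
      part$family_of[[member]]
    }
    planted <- gen$ground_truth$planted
    vapply(seq_len(nrow(planted)), function(i) {
      row <- sc[sc$query_family == fam_label(planted$query_family[i]) &
                  sc$neighbor_family == fam_label(planted$neighbor_family[i]), ]
      if (nrow(row) == 0L) NA_real_ else row$score
    }, numeric(1))
  }
  s_full <- score_planted(1, 31L)
  expect_true(all(!is.na(s_full)))          # every adjacency in all 5 genomes
  expect_true(all(s_full > 0))
  s_none <- score_planted(0, 31L)
  expect_true(all(is.na(s_none)))           # never conserved in >= 3 genomes
  # conservation strengthens scores stochastically
  grid <- c(0.2, 0.5, 0.8)
  seeds <- 41:45
  means <- unlist(lapply(seeds, function(sd)
    vapply(grid, function(p) {
      s <- score_planted(p, sd)
      mean(ifelse(is.na(s), 0, s))   # unscored = no observed conservation
    }, numeric(1))))
  probs <- rep(grid, times = length(seeds))
  expect_gt(stats::cor(probs, means, method = "spearman"), 0.8)
})

test_that("the four-genome toy has the intended family structure", {
  toy <- regenerate_fig1_toy()
  parts <- cluster_families(toy$hits, toy$collection)
  f10 <- parts[["1e-10"]]$family_of
  expect_equal(length(unique(f10[toy$toy_families$query])), 1L)
  expect_equal(length(unique(f10[c(toy$toy_families$c1_at_1e50,
                                   toy$toy_families$c4_at_1e50)])), 1L)
  f50 <- parts[["1e-50"]]$family_of
  expect_equal(length(unique(f50[toy$toy_families$query])), 1L)
  expect_false(f50[["a1"]] == f50[["a3"]])   # c1 splits from c4
  f100 <- parts[["1e-100"]]$family_of
  expect_equal(sum(f100 == f100[["q1"]]), 1L)  # query 1 isolated
  expect_equal(length(unique(f100[c("q2", "q3", "q4")])), 1L)
})
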