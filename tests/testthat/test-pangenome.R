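test_that("blast_distance reproduces the reciprocal-score formula", {
  ps <- new_pair_scores(data.frame(
    query = c("A", "B", "A", "B"), subject = c("A", "B", "B", "A"),
    score = c(100, 100, 50, 60)
  ))
  d <- blast_distance(ps, c("A", "B"))
  expect_equal(d["A", "B"], 1 - 0.5 * (50 / 100 + 60 / 100))  # 0.45
  expect_equal(d["B", "A"], 0.45)
  expect_equal(diag(d), c(A = 0, B = 0))
})

test_that("identical genes sit at distance 0, unaligned pairs at 1", {
  ps <- new_pair_scores(data.frame(
    query = c("A", "B", "A", "B", "C"),
    subject = c("A", "B", "B", "A", "C"),
    score = c(80, 80, 80, 80, 33)
  ))
  d <- blast_distance(ps, c("A", "B", "C"))
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 1)  # no hit either direction
  expect_error(blast_distance(ps, c("A", "D")), "self score")
})

test_that("blast_distance is symmetric, zero-diagonal and in [0,1] on random contract-satisfying tables", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    ps <- random_score_table(n)
    d <- blast_distance(ps, unique(ps$query))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("complete linkage groups close genes and refuses chained merges", {
  ids <- c("A", "B", "C")
  d1 <- matrix(0.1, 3, 3, dimnames = list(ids, ids)); diag(d1) <- 0
  expect_equal(dplyr::n_distinct(complete_linkage_families(d1)$family_id), 1L)

  d2 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, dimnames = list(ids, ids))
  fam2 <- complete_linkage_families(d2)
  expect_identical(families_as_partition(fam2), list(c("A", "B"), "C"))

  # chain A-B 0.5, B-C 0.5, A-C 0.8: complete linkage refuses the 0.8 merge
  d3 <- matrix(c(0, .5, .8, .5, 0, .5, .8, .5, 0), 3, dimnames = list(ids, ids))
  fam3 <- complete_linkage_families(d3)
  expect_identical(families_as_partition(fam3), list(c("A", "B"), "C"))

  expect_error(complete_linkage_families(matrix(c(0, 1, 0, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B")))), "symmetric")
})

test_that("complete linkage matches the brute-force oracle on random matrices", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    ids <- sprintf("g%02d", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    thr <- runif(1, 0.2, 0.9)
    got <- families_as_partition(complete_linkage_families(d, thr))
    expect_identical(got, oracle_complete_linkage(d, thr))
  }
})

test_that("clustering output is invariant to gene order and threshold 0 isolates all genes", {
  set.seed(7)
  n <- 8
  ids <- sprintf("g%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  perm <- sample(n)
  expect_identical(complete_linkage_families(d, 0.75),
                   complete_linkage_families(d[perm, perm], 0.75))
  expect_equal(dplyr::n_distinct(complete_linkage_families(d, 0)$family_id), n)
})

test_that("internal scorer obeys the contract and finds the planted structure", {
  sc <- score_pairs(c(a = "MKVLH", b = "MKVLH", c = "WWWWW"))
  df <- as.data.frame(sc)
  self <- with(df, score[query == subject])
  names(self) <- with(df, query[query == subject])
  expect_true(all(df$score <= self[df$query] + 1e-9))
  # closed form: gap-free self-alignment score is the sum of BLOSUM62
  # diagonal entries (M=5, K=5, V=4, L=4, H=8 -> 26; W=11 -> 55)
  expect_equal(unname(self[c("a", "c")]), c(26, 55))
  expect_equal(df$score[df$query == "a" & df$subject == "b"], 26)
  # identical proteins: cross score equals self score -> distance 0
  d <- blast_distance(sc, c("a", "b", "c"))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)   # no positive-scoring alignment survives
  expect_error(score_pairs(c(a = "")), "empty")
})

test_that("pan matrix counts genes per family per strain", {
  fam <- tibble::tibble(family_id = c("F1", "F1", "F2", "F2"),
                        gene_id = c("g1", "g2", "g3", "g4"))
  map <- c(g1 = "sA", g2 = "sB", g3 = "sA", g4 = "sA")
  pan <- build_pan_matrix(fam, map)
  expect_equal(pan["F1", ], c(sA = 1L, sB = 0L) + c(sA = 0L, sB = 1L))
  expect_equal(pan["F2", "sA"], 2L)  # paralogs count individually
  expect_equal(rowSums(pan), c(F1 = 2L, F2 = 2L))
  expect_error(build_pan_matrix(fam, map[-1]), "not in gene map")
  pan0 <- build_pan_matrix(fam[0, ], map, strains = c("sA", "sB"))
  expect_equal(nrow(pan0), 0L)
})

test_that("core/accessory labels follow the exact presence ratio rule", {
  cases <- list(
    list(n = 10, presence = 10, label = "core"),
    list(n = 10, presence = 9, label = "accessory"),
    list(n = 20, presence = 19, label = "core"),       # 0.95 boundary
    list(n = 20, presence = 18, label = "accessory"),
    list(n = 62, presence = 59, label = "core"),       # 59/62 ~ 0.9516
    list(n = 62, presence = 58, label = "accessory"),
    list(n = 10, presence = 1, label = "singleton")
  )
  for (cs in cases) {
    pf <- planted_families(cs$n, cs$presence)
    pan <- build_pan_matrix(pf$families, pf$gene_map)
    part <- partition_core_accessory(pan, pf$families, pf$gene_map)
    expect_identical(
      part$family_label$label[part$family_label$family_id == "Ftest"],
      cs$label
    )
  }
  pf <- planted_families(4, 2)
  pan <- build_pan_matrix(pf$families, pf$gene_map)
  expect_error(partition_core_accessory(pan, pf$families, pf$gene_map,
                                        core_frac = 1.5), "core_frac")
})

test_that("singletons are excluded from core/accessory but kept in whole", {
  pf <- planted_families(10, 1)
  pan <- build_pan_matrix(pf$families, pf$gene_map)
  part <- partition_core_accessory(pan, pf$families, pf$gene_map)
  g <- part$genes
  single_gene <- "s01_gT"
  expect_false(single_gene %in% g$gene_id[g$region %in% c("core", "accessory")])
  expect_true(single_gene %in% g$gene_id[g$region == "whole"])
  part2 <- partition_core_accessory(pan, pf$families, pf$gene_map,
                                    whole_includes_singletons = FALSE)
  expect_false(single_gene %in% part2$genes$gene_id)
})

test_that("per-strain region sets are disjoint and contained in whole", {
  set.seed(33)
  spec <- sim_spec(n_phyla = 1, n_genera_per_phylum = 1,
                   n_species_per_genus = 1, n_strains_per_species = 6,
                   n_core_families = 8, n_accessory_families = 4,
                   n_singletons_per_strain = 1, gene_len_mean = 90,
                   mutation_rate_within_family = 0, seed = 33)
  sim <- simulate_pangenome(spec)
  map <- stats::setNames(sim$genes$strain_id, sim$genes$gene_id)
  fam <- cluster_pangenome(stats::setNames(sim$genes$aa_seq, sim$genes$gene_id),
                           map, sim$meta)
  pan <- build_pan_matrix(fam, map)
  part <- partition_core_accessory(pan, fam, map)
  for (s in unique(sim$genes$strain_id)) {
    g <- part$genes[part$genes$strain_id == s, ]
    core <- g$gene_id[g$region == "core"]
    acc <- g$gene_id[g$region == "accessory"]
    whole <- g$gene_id[g$region == "whole"]
    expect_length(intersect(core, acc), 0)
    expect_true(all(core %in% whole) && all(acc %in% whole))
  }
})

test_that("partition labels are invariant to row/column order", {
  pf <- planted_families(10, 5)
  pan <- build_pan_matrix(pf$families, pf$gene_map)
  part1 <- partition_core_accessory(pan, pf$families, pf$gene_map)
  perm_r <- rev(seq_len(nrow(pan)))
  perm_c <- rev(seq_len(ncol(pan)))
  part2 <- partition_core_accessory(pan[perm_r, perm_c], pf$families,
                                    pf$gene_map)
  expect_identical(part1$family_label, part2$family_label)
})

test_that("core_fraction is the length-weighted share of core genes", {
  pf <- planted_families(10, 10)       # Ftest core (10/10), Fall core
  pan <- build_pan_matrix(pf$families, pf$gene_map)
  part <- partition_core_accessory(pan, pf$families, pf$gene_map)
  lens <- stats::setNames(rep(300L, length(pf$gene_map)), names(pf$gene_map))
  expect_equal(unname(core_fraction(part, lens, "s01")), 1.0)
  # make Ftest accessory: presence 5/10
  pf2 <- planted_families(10, 5)
  pan2 <- build_pan_matrix(pf2$families, pf2$gene_map)
  part2 <- partition_core_accessory(pan2, pf2$families, pf2$gene_map)
  lens2 <- stats::setNames(rep(100L, length(pf2$gene_map)), names(pf2$gene_map))
  lens2["s01_gA"] <- 970L
  lens2["s01_gT"] <- 30L
  expect_equal(unname(core_fraction(part2, lens2, "s01")), 0.97)
})
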