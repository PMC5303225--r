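test_that("taxonomy is balanced, deterministic and matches the tree", {
  spec <- sim_spec(n_phyla = 2, n_genera_per_phylum = 2,
                   n_species_per_genus = 2, n_strains_per_species = 3,
                   seed = 12)
  tax <- simulate_taxonomy(spec)
  expect_equal(nrow(tax$meta), 24L)
  expect_equal(dplyr::n_distinct(tax$meta$species), 8L)
  expect_equal(dplyr::n_distinct(tax$meta$genus), 4L)
  expect_setequal(tax$tree$tip.label, unique(tax$meta$species))
  expect_true(ape::is.ultrametric(tax$tree))
  tax2 <- simulate_taxonomy(spec)
  expect_identical(tax$meta, tax2$meta)
  expect_identical(ape::write.tree(tax$tree), ape::write.tree(tax2$tree))
})

test_that("sim_spec validates its fields", {
  expect_error(sim_spec(n_phyla = 0), ">= 1")
  expect_error(sim_spec(gene_len_mean = 100), "multiple of 3")
  expect_error(sim_spec(gc_core = 1.2), "in \\(0, 1\\)")
  expect_error(sim_spec(accessory_presence_prob = 1), "in \\(0, 1\\)")
  expect_error(sim_spec(mutation_rate_within_family = 0.5), "\\[0, 0.2\\]")
})

test_that("simulated sequences hit the GC target and stay stop-free", {
  set.seed(1)
  s <- simulate_sequences(3e5, 0.5)
  expect_lt(abs(gc_content(s) - 0.5), 0.005)
  # small structural floor: conditioning codons on "not a stop" leaves a
  # faint trinucleotide signature even at bias 0
  expect_lt(relative_entropy(s), 5e-3)
  # no in-frame stop codons anywhere
  codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  expect_length(intersect(codons, c("TAA", "TAG", "TGA")), 0)
  expect_error(simulate_sequences(300, 0), "infeasible")
})

test_that("codon bias raises relative entropy at matched GC and length", {
  set.seed(2)
  plain <- simulate_sequences(2e5, 0.5, trinuc_bias = 0)
  biased <- simulate_sequences(2e5, 0.5, trinuc_bias = 1)
  expect_gt(relative_entropy(biased), relative_entropy(plain))
  expect_equal(gc_content(biased), 0.5, tolerance = 0.02)
})

test_that("mosaic blocks raise gcvar at matched overall GC", {
  set.seed(3)
  hom <- simulate_sequences(6e4, 0.5)
  mos <- simulate_sequences(6e4, 0.5, mosaic_block_len = 500,
                            mosaic_amplitude = 0.15)
  expect_gt(as.numeric(gcvar(mos)), as.numeric(gcvar(hom)))
  expect_equal(gc_content(mos), 0.5, tolerance = 0.02)
})

test_that("zero mutation rate gives identical family members at distance 0", {
  spec <- sim_spec(n_phyla = 1, n_genera_per_phylum = 1,
                   n_species_per_genus = 1, n_strains_per_species = 4,
                   n_core_families = 3, n_accessory_families = 0,
                   n_singletons_per_strain = 0, gene_len_mean = 90,
                   mutation_rate_within_family = 0, seed = 9)
  sim <- simulate_pangenome(spec)
  by_fam <- split(sim$genes$nt_seq, sim$truth$gene_classes$family_id[
    match(sim$genes$gene_id, sim$truth$gene_classes$gene_id)])
  for (f in by_fam) expect_equal(dplyr::n_distinct(f), 1L)
})

test_that("pipeline recovers the planted families and labels exactly", {
  spec <- sim_spec(n_phyla = 1, n_genera_per_phylum = 1,
                   n_species_per_genus = 1, n_strains_per_species = 10,
                   n_core_families = 12, n_accessory_families = 8,
                   n_singletons_per_strain = 1, gene_len_mean = 120,
                   mutation_rate_within_family = 0.01, seed = 14)
  sim <- simulate_pangenome(spec)
  map <- stats::setNames(sim$genes$strain_id, sim$genes$gene_id)
  fam <- cluster_pangenome(stats::setNames(sim$genes$aa_seq, sim$genes$gene_id),
                           map, sim$meta)
  # recovered family count equals planted count (incl. singleton families)
  expect_equal(dplyr::n_distinct(fam$family_id), nrow(sim$truth$families))
  # recovered partition == planted partition
  truth_part <- families_as_partition(
    tibble::tibble(family_id = sim$truth$gene_classes$family_id,
                   gene_id = sim$truth$gene_classes$gene_id))
  expect_identical(families_as_partition(fam), truth_part)
  # labels follow the planted classes
  pan <- build_pan_matrix(fam, map)
  part <- partition_core_accessory(pan, fam, map)
  got <- part$family_label
  truth_by_gene <- sim$truth$gene_classes
  one_gene <- fam$gene_id[match(got$family_id, fam$family_id)]
  true_class <- truth_by_gene$class[match(one_gene, truth_by_gene$gene_id)]
  expect_identical(got$label, true_class)
})

test_that("an accessory family planted in 9 of 10 strains stays accessory", {
  pf <- planted_families(10, 9)
  pan <- build_pan_matrix(pf$families, pf$gene_map)
  part <- partition_core_accessory(pan, pf$families, pf$gene_map)
  expect_identical(part$family_label$label[
    part$family_label$family_id == "Ftest"], "accessory")
})

test_that("simulation is deterministic and round-trips through the readers", {
  spec <- sim_spec(n_phyla = 1, n_genera_per_phylum = 2,
                   n_species_per_genus = 1, n_strains_per_species = 3,
                   n_core_families = 4, n_accessory_families = 2,
                   n_singletons_per_strain = 1, gene_len_mean = 90, seed = 77)
  sim1 <- simulate_pangenome(spec)
  sim2 <- simulate_pangenome(spec)
  expect_identical(sim1$genes, sim2$genes)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim1, dir)
  nt <- read_fasta(paths$cds, "nt")
  aa <- read_fasta(paths$proteins, "aa")
  map <- read_gene_map(paths$gene_map)
  meta <- read_strain_meta(paths$meta)
  tree <- read_newick(paths$tree)
  expect_identical(unname(nt[sim1$genes$gene_id]), sim1$genes$nt_seq)
  expect_identical(unname(aa[sim1$genes$gene_id]), sim1$genes$aa_seq)
  expect_identical(unname(map[sim1$genes$gene_id]), sim1$genes$strain_id)
  expect_identical(meta, sim1$meta)
  expect_setequal(tree$tip.label, sim1$tree$tip.label)
})

test_that("composition-level simulator plants the requested GC structure", {
  tab <- simulate_composition(region_len = 2e5, delta_core_gc = 0.05, seed = 3)
  wide <- tidyr::pivot_wider(tab[c("strain_id", "region", "gc")],
                             names_from = "region", values_from = "gc")
  expect_lt(abs(mean(wide$core - wide$accessory) - 0.05), 0.002)
  # species offsets induce between-species variance well above binomial noise
  sp_means <- tapply(tab$gc[tab$region == "core"],
                     tab$species[tab$region == "core"], mean)
  expect_gt(stats::sd(sp_means), 0.005)
})

test_that("planted GC gap survives the full sequence-level pipeline", {
  spec <- sim_spec(n_phyla = 1, n_genera_per_phylum = 1,
                   n_species_per_genus = 1, n_strains_per_species = 6,
                   n_core_families = 25, n_accessory_families = 12,
                   n_singletons_per_strain = 1, gene_len_mean = 300,
                   gc_core = 0.55, gc_accessory = 0.45,
                   gc_species_sd = 0, gc_genus_sd = 0, seed = 101)
  sim <- simulate_pangenome(spec)
  map <- stats::setNames(sim$genes$strain_id, sim$genes$gene_id)
  # use planted truth as the partition to isolate the composition stage
  fam <- tibble::tibble(family_id = sim$truth$gene_classes$family_id,
                        gene_id = sim$truth$gene_classes$gene_id)
  pan <- build_pan_matrix(fam, map)
  part <- partition_core_accessory(pan, fam, map)
  comp <- composition_table(part, sim$genes)
  wide <- tidyr::pivot_wider(comp[c("strain_id", "region", "gc")],
                             names_from = "region", values_from = "gc")
  # family ancestors total ~7.5 kb core / ~3.6 kb accessory: the planted
  # 10-point gap is recovered within ancestor-level sampling noise
  expect_lt(abs(mean(wide$core - wide$accessory) - 0.10), 0.03)
  expect_true(all(wide$core > wide$whole & wide$whole > wide$accessory))
})
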