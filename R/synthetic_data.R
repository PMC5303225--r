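# Synthetic pan-genomes with known ground truth: balanced taxonomy, core /
# accessory / singleton family structure, and per-class compositional
# parameters (GC target, GC mosaicism, trinucleotide bias). Sequences are
# codon-structured with no in-frame stop codons so protein translation and
# protein-level clustering are always valid.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.GC_RICH_CODONS <- c("GCG", "CGC")  # biased-component codons, GC = 1
.AT_RICH_CODONS <- c("ATT", "TTA")  # biased-component codons, GC = 0

#' Specification of a synthetic pan-genome
#'
#' Collects every knob of the generator with validation. The defaults
#' describe a small multi-species study with the compositional contrasts
#' under investigation planted in every strain: core genes are GC-richer,
#' codon-biased and GC-homogeneous; accessory genes are AT-richer, unbiased
#' and GC-mosaic.
#'
#' @param n_phyla,n_genera_per_phylum,n_species_per_genus,n_strains_per_species
#'   Balanced taxonomy sizes.
#' @param n_core_families Core families per species (present in every
#'   strain of the species).
#' @param n_accessory_families Accessory families per species; each is
#'   present in a random strain subset (at least two strains).
#' @param n_singletons_per_strain Unique genes per strain.
#' @param accessory_presence_prob Per-strain presence probability of an
#'   accessory family, conditioned on presence in at least two strains.
#' @param gene_len_mean Mean gene length in nucleotides (multiple of 3);
#'   individual lengths vary uniformly within 30%.
#' @param gc_core,gc_accessory Target GC fractions per gene class;
#'   singletons use the accessory parameters.
#' @param gc_species_sd,gc_genus_sd Standard deviations of normal GC
#'   offsets shared by all genes of a species / genus; these create the
#'   variance-component structure the mixed models estimate.
#' @param mosaic_block_len Block length (nt) of alternating high/low GC
#'   segments in accessory genes; 0 disables mosaicism.
#' @param mosaic_amplitude GC half-amplitude of the mosaic blocks.
#' @param trinuc_bias_strength Strength of the preferred-codon reweighting
#'   in core genes; 0 means i.i.d. codons, larger values plant higher
#'   trinucleotide relative entropy at unchanged expected GC.
#' @param mutation_rate_within_family Per-site point-mutation probability
#'   applied to each family member relative to the family ancestor.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(n_phyla = 2L, n_genera_per_phylum = 2L,
                     n_species_per_genus = 2L, n_strains_per_species = 10L,
                     n_core_families = 40L, n_accessory_families = 20L,
                     n_singletons_per_strain = 2L,
                     accessory_presence_prob = 0.5,
                     gene_len_mean = 300L,
                     gc_core = 0.55, gc_accessory = 0.45,
                     gc_species_sd = 0.02, gc_genus_sd = 0.01,
                     mosaic_block_len = 150L, mosaic_amplitude = 0.15,
                     trinuc_bias_strength = 0.5,
                     mutation_rate_within_family = 0.01,
                     seed = 42L) {
  spec <- list(
    n_phyla = as.integer(n_phyla),
    n_genera_per_phylum = as.integer(n_genera_per_phylum),
    n_species_per_genus = as.integer(n_species_per_genus),
    n_strains_per_species = as.integer(n_strains_per_species),
    n_core_families = as.integer(n_core_families),
    n_accessory_families = as.integer(n_accessory_families),
    n_singletons_per_strain = as.integer(n_singletons_per_strain),
    accessory_presence_prob = accessory_presence_prob,
    gene_len_mean = as.integer(gene_len_mean),
    gc_core = gc_core, gc_accessory = gc_accessory,
    gc_species_sd = gc_species_sd, gc_genus_sd = gc_genus_sd,
    mosaic_block_len = as.integer(mosaic_block_len),
    mosaic_amplitude = mosaic_amplitude,
    trinuc_bias_strength = trinuc_bias_strength,
    mutation_rate_within_family = mutation_rate_within_family,
    seed = as.integer(seed)
  )
  counts <- c("n_phyla", "n_genera_per_phylum", "n_species_per_genus",
              "n_strains_per_species", "n_core_families", "gene_len_mean")
  for (f in counts) if (spec[[f]] < 1L) stop(f, " must be >= 1")
  if (spec$n_accessory_families < 0L) stop("n_accessory_families must be >= 0")
  if (spec$n_singletons_per_strain < 0L) stop("n_singletons_per_strain must be >= 0")
  if (spec$gene_len_mean %% 3L != 0L) stop("gene_len_mean must be a multiple of 3")
  if (spec$accessory_presence_prob <= 0 || spec$accessory_presence_prob >= 1) {
    stop("accessory_presence_prob must be in (0, 1)")
  }
  for (f in c("gc_core", "gc_accessory")) {
    if (spec[[f]] <= 0 || spec[[f]] >= 1) stop(f, " must be in (0, 1)")
  }
  if (spec$gc_species_sd < 0 || spec$gc_genus_sd < 0) stop("GC sds must be >= 0")
  if (spec$trinuc_bias_strength < 0) stop("trinuc_bias_strength must be >= 0")
  if (spec$mutation_rate_within_family < 0 || spec$mutation_rate_within_family > 0.2) {
    stop("mutation_rate_within_family must be in [0, 0.2]")
  }
  structure(spec, class = "sim_spec")
}

# Conditioning i.i.d. codons on "not a stop codon" removes AT-rich
# codons and would pull GC above target; solve for the per-base GC
# parameter whose stop-conditioned expectation equals the target.
.codon_gc_adjust <- local({
  cache <- new.env(parent = emptyenv())
  codons <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                        b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  is_stop <- paste0(codons$b1, codons$b2, codons$b3) %in% .STOP_CODONS
  n_gc <- (codons$b1 %in% c("C", "G")) + (codons$b2 %in% c("C", "G")) +
    (codons$b3 %in% c("C", "G"))
  function(gc_target) {
    key <- sprintf("%.10f", gc_target)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- function(g) {
      pb <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
      p <- pb[codons$b1] * pb[codons$b2] * pb[codons$b3]
      sum(p[!is_stop] * n_gc[!is_stop]) / (3 * sum(p[!is_stop])) - gc_target
    }
    g <- stats::uniroot(f, c(0.005, 0.995), tol = 1e-10)$root
    cache[[key]] <- g
    g
  }
})

# One block of i.i.d. codons at target GC, optionally mixed with the
# preferred-codon component; never emits an in-frame stop codon.
.sample_codon_block <- function(n_codons, gc, bias_w = 0) {
  gc <- as.numeric(gc)[1]
  if (gc <= 0 || gc >= 1) stop("infeasible GC target: ", gc)
  g <- .codon_gc_adjust(gc)
  pr <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  b <- matrix(sample(names(pr), 3L * n_codons, replace = TRUE, prob = pr),
              nrow = 3L)
  repeat {
    stops <- which(b[1L, ] == "T" &
                     ((b[2L, ] == "A" & b[3L, ] %in% c("A", "G")) |
                        (b[2L, ] == "G" & b[3L, ] == "A")))
    if (!length(stops)) break
    b[, stops] <- sample(names(pr), 3L * length(stops), replace = TRUE, prob = pr)
  }
  if (bias_w > 0) {
    biased <- which(stats::runif(n_codons) < bias_w)
    if (length(biased)) {
      # preferred set is half GC-rich, half AT-rich codons, mixed with
      # probability gc so the expected GC stays on target
      rich <- stats::runif(length(biased)) < gc
      cod <- character(length(biased))
      if (any(rich)) cod[rich] <- sample(.GC_RICH_CODONS, sum(rich), replace = TRUE)
      if (any(!rich)) cod[!rich] <- sample(.AT_RICH_CODONS, sum(!rich), replace = TRUE)
      b[, biased] <- matrix(unlist(strsplit(cod, "")), nrow = 3L)
    }
  }
  b
}

#' Simulate one codon-structured nucleotide sequence
#'
#' Draws codons to hit the target GC in expectation. `trinuc_bias > 0`
#' mixes in a fixed GC-balanced preferred-codon set with weight
#' `bias/(1+bias)`, raising trinucleotide relative entropy without moving
#' expected GC. `mosaic_block_len > 0` alternates blocks of GC
#' `gc + amplitude` and `gc - amplitude`, raising GCVAR at unchanged
#' overall GC. No in-frame stop codons are ever produced. Uses the current
#' RNG stream; seed at the caller.
#'
#' @param length Sequence length in nt (rounded up to a codon multiple).
#' @param gc Target GC fraction in (0, 1).
#' @param mosaic_block_len Mosaic block length in nt (0 = homogeneous).
#' @param mosaic_amplitude GC half-amplitude of mosaic blocks.
#' @param trinuc_bias Preferred-codon bias strength (>= 0).
#' @return A single nucleotide string.
#' @export
simulate_sequences <- function(length, gc, mosaic_block_len = 0L,
                               mosaic_amplitude = 0.15, trinuc_bias = 0) {
  stopifnot(length >= 3)
  n_codons <- as.integer(ceiling(length / 3))
  bias_w <- trinuc_bias / (1 + trinuc_bias)
  if (mosaic_block_len > 0L) {
    block_codons <- max(1L, as.integer(round(mosaic_block_len / 3)))
    n_blocks <- ceiling(n_codons / block_codons)
    hi <- min(gc + mosaic_amplitude, 0.98)
    lo <- max(gc - mosaic_amplitude, 0.02)
    # random starting phase keeps the marginal GC on target even when the
    # last block is truncated
    phase <- sample(0:1, 1L)
    parts <- lapply(seq_len(n_blocks), function(k) {
      nc <- min(block_codons, n_codons - (k - 1L) * block_codons)
      .sample_codon_block(nc, if ((k + phase) %% 2L == 1L) hi else lo, bias_w)
    })
    b <- do.call(cbind, parts)
  } else {
    b <- .sample_codon_block(n_codons, gc, bias_w)
  }
  paste(b, collapse = "")
}

# Point mutations at the given per-site rate; any stop codon created by a
# mutation is resampled from uniform non-stop codons (rare at small rates).
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    b[hit] <- vapply(b[hit], function(x) sample(alt[[x]], 1L), character(1))
    m <- matrix(b, nrow = 3L)
    repeat {
      stops <- which(m[1L, ] == "T" &
                       ((m[2L, ] == "A" & m[3L, ] %in% c("A", "G")) |
                          (m[2L, ] == "G" & m[3L, ] == "A")))
      if (!length(stops)) break
      m[, stops] <- sample(c("A", "C", "G", "T"), 3L * length(stops),
                           replace = TRUE)
    }
    b <- as.vector(m)
  }
  paste(b, collapse = "")
}

.taxonomy_impl <- function(spec) {
  phyla <- sprintf("P%02d", seq_len(spec$n_phyla))
  rows <- list()
  species_ids <- character(0)
  for (p in phyla) {
    for (g in seq_len(spec$n_genera_per_phylum)) {
      genus <- sprintf("%s_G%02d", p, g)
      for (s in seq_len(spec$n_species_per_genus)) {
        sp <- sprintf("%s_S%02d", genus, s)
        species_ids <- c(species_ids, sp)
        rows[[sp]] <- tibble::tibble(
          strain_id = sprintf("%s_st%02d", sp,
                              seq_len(spec$n_strains_per_species)),
          species = sp, genus = genus, phylum = p
        )
      }
    }
  }
  meta <- dplyr::bind_rows(rows)
  # a coalescent tree needs >= 2 leaves; single-species runs carry no tree
  tree <- if (length(species_ids) >= 2L) {
    ape::rcoal(length(species_ids), tip.label = species_ids)
  }
  list(meta = meta, tree = tree)
}

#' Simulate a balanced taxonomy and an ultrametric species tree
#'
#' @param spec A [sim_spec()].
#' @return List with `meta` (strain metadata tibble) and `tree` (random
#'   ultrametric coalescent tree with one leaf per species).
#' @export
simulate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  .taxonomy_impl(spec)
}

.draw_gene_len <- function(spec) {
  nc <- spec$gene_len_mean / 3L
  3L * max(10L, as.integer(round(stats::runif(1, 0.7, 1.3) * nc)))
}

.clamp_gc <- function(x) pmin(pmax(x, 0.05), 0.95)

#' Simulate a full pan-genome with known truth
#'
#' For every species, core families are present in all strains, accessory
#' families in a random subset of at least two strains (per-strain presence
#' probability `accessory_presence_prob`), and each strain receives unique
#' singleton genes. Within a family, members derive from a common ancestor
#' by point mutations at `mutation_rate_within_family`, so intra-family
#' distances are small and inter-family distances large. Core ancestors use
#' the core compositional parameters (GC target plus genus/species offsets,
#' trinucleotide bias); accessory and singleton genes use the accessory
#' parameters (GC target plus offsets, mosaic blocks). Proteins come from
#' [translate_cds()] (translation table 11).
#'
#' @param spec A [sim_spec()].
#' @return List with `genes` (tibble `gene_id`, `strain_id`, `nt_seq`,
#'   `aa_seq`), `meta`, `tree`, `truth` (list with `families`: tibble
#'   `family_id`, `species`, `class`, `gc_target`, and `gene_classes`:
#'   tibble `gene_id`, `family_id`, `class`) and the `spec`.
#' @export
simulate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  tax <- .taxonomy_impl(spec)
  meta <- tax$meta
  genera <- unique(meta$genus)
  genus_off <- stats::setNames(stats::rnorm(length(genera), 0, spec$gc_genus_sd),
                               genera)
  species <- unique(meta$species)
  sp_off <- stats::setNames(stats::rnorm(length(species), 0, spec$gc_species_sd),
                            species)
  gene_rows <- list()
  fam_rows <- list()
  class_rows <- list()
  gene_counter <- stats::setNames(integer(nrow(meta)), meta$strain_id)
  next_gene_id <- function(strain) {
    gene_counter[strain] <<- gene_counter[strain] + 1L
    sprintf("%s_g%04d", strain, gene_counter[strain])
  }
  for (sp in species) {
    strains <- meta$strain_id[meta$species == sp]
    n_str <- length(strains)
    off <- genus_off[meta$genus[match(sp, meta$species)]] + sp_off[sp]
    gc_core_sp <- .clamp_gc(spec$gc_core + off)
    gc_acc_sp <- .clamp_gc(spec$gc_accessory + off)
    emit_family <- function(fam_idx, class, members) {
      len <- .draw_gene_len(spec)
      if (class == "core") {
        anc <- simulate_sequences(len, gc_core_sp,
                                  trinuc_bias = spec$trinuc_bias_strength)
        gc_target <- gc_core_sp
      } else {
        anc <- simulate_sequences(len, gc_acc_sp,
                                  mosaic_block_len = spec$mosaic_block_len,
                                  mosaic_amplitude = spec$mosaic_amplitude)
        gc_target <- gc_acc_sp
      }
      fam_id <- sprintf("%s_fam%04d", sp, fam_idx)
      fam_rows[[fam_id]] <<- tibble::tibble(
        family_id = fam_id, species = sp, class = class, gc_target = gc_target
      )
      for (st in members) {
        gid <- next_gene_id(st)
        nt <- .mutate_seq(anc, spec$mutation_rate_within_family)
        gene_rows[[gid]] <<- tibble::tibble(gene_id = gid, strain_id = st,
                                            nt_seq = nt)
        class_rows[[gid]] <<- tibble::tibble(gene_id = gid, family_id = fam_id,
                                             class = class)
      }
    }
    fam_idx <- 0L
    for (f in seq_len(spec$n_core_families)) {
      fam_idx <- fam_idx + 1L
      emit_family(fam_idx, "core", strains)
    }
    if (spec$n_accessory_families > 0L && n_str < 2L) {
      stop("accessory families need at least 2 strains per species")
    }
    for (f in seq_len(spec$n_accessory_families)) {
      fam_idx <- fam_idx + 1L
      repeat {
        present <- strains[stats::runif(n_str) < spec$accessory_presence_prob]
        if (length(present) >= 2L) break
      }
      emit_family(fam_idx, "accessory", present)
    }
    if (spec$n_singletons_per_strain > 0L) {
      for (st in strains) {
        for (k in seq_len(spec$n_singletons_per_strain)) {
          fam_idx <- fam_idx + 1L
          emit_family(fam_idx, "singleton", st)
        }
      }
    }
  }
  genes <- dplyr::bind_rows(gene_rows)
  genes$aa_seq <- as.character(translate_cds(stats::setNames(genes$nt_seq,
                                                             genes$gene_id)))
  list(genes = genes, meta = meta, tree = tax$tree,
       truth = list(families = dplyr::bind_rows(fam_rows),
                    gene_classes = dplyr::bind_rows(class_rows)),
       spec = spec)
}

#' Simulate a composition table directly (no sequences)
#'
#' Fast generator for calibrating the statistical layer: per-strain,
#' per-region GC values are drawn as binomial base counts at the planted
#' region probabilities, which is distributionally identical to measuring
#' GC on i.i.d. simulated sequences of the same pooled length, at a
#' fraction of the cost. Species and genus GC offsets are drawn from
#' normal distributions to create the nested variance components. The
#' `whole` region mixes core and accessory probabilities with weight
#' `core_weight`.
#'
#' @param n_phyla,n_genera_per_phylum,n_species_per_genus,n_strains_per_species
#'   Balanced taxonomy sizes (defaults give 20 species, 200 strains).
#' @param gc_accessory Baseline accessory GC fraction.
#' @param delta_core_gc Planted core-minus-accessory GC difference
#'   (fraction; 0.02 = 2 percentage points).
#' @param core_weight Core share of the whole region.
#' @param region_len Pooled nucleotide length per region per strain.
#' @param gc_species_sd,gc_genus_sd Normal GC offset sds.
#' @param seed Integer seed.
#' @return Tibble with `strain_id`, `species`, `genus`, `phylum`,
#'   `region`, `gc` (fraction) and `total_len`, three rows per strain.
#' @export
simulate_composition <- function(n_phyla = 2L, n_genera_per_phylum = 5L,
                                 n_species_per_genus = 2L,
                                 n_strains_per_species = 10L,
                                 gc_accessory = 0.45, delta_core_gc = 0.02,
                                 core_weight = 0.8, region_len = 1e5,
                                 gc_species_sd = 0.02, gc_genus_sd = 0.01,
                                 seed = 1L) {
  set.seed(seed)
  spec <- sim_spec(n_phyla = n_phyla, n_genera_per_phylum = n_genera_per_phylum,
                   n_species_per_genus = n_species_per_genus,
                   n_strains_per_species = n_strains_per_species)
  meta <- .taxonomy_impl(spec)$meta
  genera <- unique(meta$genus)
  genus_off <- stats::setNames(stats::rnorm(length(genera), 0, gc_genus_sd),
                               genera)
  species <- unique(meta$species)
  sp_off <- stats::setNames(stats::rnorm(length(species), 0, gc_species_sd),
                            species)
  L <- as.integer(region_len)
  off <- unname(genus_off[meta$genus] + sp_off[meta$species])
  p_acc <- .clamp_gc(gc_accessory + off)
  p_core <- .clamp_gc(p_acc + delta_core_gc)
  p_whole <- core_weight * p_core + (1 - core_weight) * p_acc
  n <- nrow(meta)
  out <- tibble::tibble(
    strain_id = rep(meta$strain_id, each = 3L),
    species = rep(meta$species, each = 3L),
    genus = rep(meta$genus, each = 3L),
    phylum = rep(meta$phylum, each = 3L),
    region = rep(c("accessory", "whole", "core"), times = n),
    gc = stats::rbinom(3L * n, L,
                       as.vector(rbind(p_acc, p_whole, p_core))) / L,
    total_len = L
  )
  out
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Draws one trait value per leaf from a multivariate normal with the
#' Brownian covariance of the tree (`sigma^2 * vcv(tree)`) around a mean
#' vector, i.e. full phylogenetic signal (Pagel's lambda = 1).
#'
#' @param tree `ape::phylo` tree with branch lengths.
#' @param mean Scalar or per-leaf mean vector (in leaf order).
#' @param sigma Brownian diffusion standard deviation per unit branch
#'   length.
#' @return Named numeric vector of leaf trait values.
#' @export
simulate_bm_trait <- function(tree, mean = 0, sigma = 1) {
  V <- ape::vcv(tree) * sigma^2
  z <- stats::rnorm(nrow(V))
  y <- drop(t(chol(V)) %*% z) + mean
  stats::setNames(y, rownames(V))
}

#' Write a simulated pan-genome to pipeline input files
#'
#' Emits exactly the formats the pipeline consumes: nucleotide FASTA,
#' protein FASTA, gene-to-strain TSV, strain metadata TSV and a Newick
#' species tree, plus the ground-truth tables for evaluation.
#'
#' @param sim Result of [simulate_pangenome()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cds = file.path(dir, "cds.fasta"),
    proteins = file.path(dir, "proteins.fasta"),
    gene_map = file.path(dir, "gene_map.tsv"),
    meta = file.path(dir, "meta.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth_families = file.path(dir, "truth_families.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  write_fasta(stats::setNames(sim$genes$nt_seq, sim$genes$gene_id), paths$cds)
  write_fasta(stats::setNames(sim$genes$aa_seq, sim$genes$gene_id),
              paths$proteins)
  write_tsv_canonical(sim$genes[c("gene_id", "strain_id")], paths$gene_map)
  write_tsv_canonical(sim$meta, paths$meta)
  if (!is.null(sim$tree)) {
    ape::write.tree(sim$tree, paths$tree)
  } else {
    paths$tree <- NULL
  }
  write_tsv_canonical(sim$truth$families, paths$truth_families)
  write_tsv_canonical(sim$truth$gene_classes, paths$truth_genes)
  invisible(paths)
}
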