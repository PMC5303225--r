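# Gene families from pairwise similarity scores, and the core/accessory
# partition of the resulting pan-genome.

#' Score all protein pairs with a local aligner
#'
#' Computes Smith-Waterman local-alignment scores (BLOSUM62, gap opening 11,
#' gap extension 1, raw score) for every unordered pair of proteins plus all
#' self pairs. Raw scores are symmetric, so both ordered directions of a
#' pair carry the same score. Pairs with no positive-scoring local alignment
#' are omitted and are treated downstream as similarity 0 (distance 1).
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param gap_opening,gap_extension Affine gap penalties (BLAST protein
#'   defaults).
#' @param substitution_matrix Name of the scoring matrix (default
#'   `"BLOSUM62"`).
#' @return A `pair_scores` tibble (see [new_pair_scores()]) with
#'   `scorer = "smith-waterman"`.
#' @export
score_pairs <- function(proteins, gap_opening = 11, gap_extension = 1,
                        substitution_matrix = "BLOSUM62") {
  stopifnot(is.character(proteins), length(proteins) >= 1L,
            !is.null(names(proteins)))
  if (any(!nzchar(proteins))) stop("empty protein sequence(s)")
  ids <- sort(names(proteins))
  aa <- Biostrings::AAStringSet(proteins[ids])
  e <- new.env()
  utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
  mat <- get(substitution_matrix, envir = e)
  n <- length(aa)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = aa[i:n], subject = aa[[i]], type = "local",
      substitutionMatrix = mat, gapOpening = gap_opening,
      gapExtension = gap_extension, scoreOnly = TRUE
    )
    keep <- which(sc > 0 | seq_along(sc) == 1L)
    j <- (i:n)[keep]
    rows[[i]] <- data.frame(query = ids[i], subject = ids[j], score = sc[keep])
  }
  df <- do.call(rbind, rows)
  self <- df$score[match(paste(ids, ids), paste(df$query, df$subject))]
  names(self) <- ids
  if (any(is.na(self) | self <= 0)) {
    stop("internal scorer error: missing or non-positive self score")
  }
  if (any(df$score > pmin(self[df$query], self[df$subject]) + 1e-9)) {
    stop("internal scorer error: cross score exceeds a self score")
  }
  # mirror the upper triangle so both ordered directions are present
  off <- df[df$query != df$subject, ]
  mirrored <- rbind(df, data.frame(query = off$subject, subject = off$query,
                                   score = off$score))
  mirrored <- mirrored[order(mirrored$query, mirrored$subject), ]
  new_pair_scores(mirrored, scorer = "smith-waterman")
}

#' BLAST-distance matrix from pairwise similarity scores
#'
#' For genes A and B with alignment scores b(A;B) (A as query), the
#' distance is
#' \deqn{d(A,B) = 1 - \frac{1}{2}\left(\frac{b(A;B)}{b(A;A)} +
#'   \frac{b(B;A)}{b(B;B)}\right)}
#' where b(A;A) is the self-alignment (maximum) score. A missing cross pair
#' is taken as score 0, so mutually unaligned genes sit at distance 1. The
#' result is clamped into [0, 1].
#'
#' @param scores A `pair_scores` tibble.
#' @param genes Character vector of gene ids to include; every gene must
#'   have a positive self score in `scores`.
#' @return Symmetric numeric matrix of distances with zero diagonal,
#'   dimnames `genes` (in sorted order).
#' @export
blast_distance <- function(scores, genes) {
  stopifnot(inherits(scores, "pair_scores"), length(genes) >= 1L)
  genes <- sort(unique(genes))
  n <- length(genes)
  b <- matrix(0, n, n, dimnames = list(genes, genes))
  keep <- scores$query %in% genes & scores$subject %in% genes
  qi <- match(scores$query[keep], genes)
  si <- match(scores$subject[keep], genes)
  b[cbind(qi, si)] <- scores$score[keep]
  self <- diag(b)
  if (any(self <= 0)) {
    stop("missing or zero self score for gene(s): ",
         paste(utils::head(genes[self <= 0], 5), collapse = ", "))
  }
  bn <- b / self            # row-recycled: bn[i, j] = b(i; j) / b(i; i)
  d <- 1 - 0.5 * (bn + t(bn))
  d <- pmin(pmax(d, 0), 1)
  diag(d) <- 0
  d
}

#' Cluster genes into families by complete linkage
#'
#' Agglomerative complete-linkage clustering of the BLAST-distance matrix,
#' cut strictly below `threshold`: a gene belongs to a family only if its
#' distance to every other member is below the threshold (the
#' complete-linkage merge height is the maximum pairwise member distance).
#' Genes are processed in lexicographic id order so the output is
#' deterministic regardless of input order.
#'
#' @param dist Symmetric distance matrix with gene ids as dimnames.
#' @param threshold Merge cut-off (default 0.75); merges at height `>=`
#'   threshold are refused. A threshold of 0 therefore leaves every gene in
#'   its own family.
#' @return Tibble with columns `family_id`, `gene_id`; family ids are
#'   `F%05d` numbered by the lexicographically smallest member.
#' @export
complete_linkage_families <- function(dist, threshold = 0.75) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (is.null(rownames(dist))) stop("distance matrix needs gene ids as dimnames")
  if (max(abs(dist - t(dist))) > 1e-9) stop("distance matrix is not symmetric")
  ord <- order(rownames(dist))
  dist <- dist[ord, ord, drop = FALSE]
  ids <- rownames(dist)
  n <- length(ids)
  if (n == 1L || threshold <= 0) {
    cl <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::as.dist(dist), method = "complete")
    # strict cut: a merge at height exactly == threshold is excluded
    cl <- stats::cutree(hc, h = threshold - 1e-10)
  }
  first <- ids[!duplicated(cl)]                 # smallest member per cluster
  fam_rank <- match(cl, cl[!duplicated(cl)])    # clusters ordered by first member
  out <- tibble::tibble(
    family_id = sprintf("F%05d", fam_rank),
    gene_id = ids
  )
  out[order(out$family_id, out$gene_id), ]
}

#' Cluster a multi-group pan-genome
#'
#' Runs [blast_distance()] + [complete_linkage_families()] separately within
#' each pan-genome group (each species, or each genus), which is how the
#' analysis is defined: gene families never span groups. Scores can be
#' imported (BLAST tabular) or computed internally with [score_pairs()];
#' the two must not be mixed.
#'
#' @param proteins Named character vector of protein sequences (all genes).
#' @param gene_map Named character vector gene id -> strain id.
#' @param meta Strain metadata tibble.
#' @param level Grouping level, `"species"` (default) or `"genus"`.
#' @param scores Optional precomputed `pair_scores`; when `NULL` the
#'   internal aligner is used.
#' @param threshold Complete-linkage cut (default 0.75).
#' @return Tibble with columns `group`, `family_id`, `gene_id`, `strain_id`;
#'   family ids are prefixed by the group so they are globally unique.
#' @export
cluster_pangenome <- function(proteins, gene_map, meta,
                              level = c("species", "genus"),
                              scores = NULL, threshold = 0.75) {
  level <- match.arg(level)
  validate_cross_refs(names(proteins), gene_map, meta)
  strain_group <- stats::setNames(meta[[level]], meta$strain_id)
  gene_group <- strain_group[gene_map[names(proteins)]]
  out <- lapply(sort(unique(gene_group)), function(g) {
    gids <- names(proteins)[gene_group == g]
    sc <- if (is.null(scores)) score_pairs(proteins[gids]) else scores
    d <- blast_distance(sc, gids)
    fam <- complete_linkage_families(d, threshold = threshold)
    tibble::tibble(
      group = g,
      family_id = paste0(g, "_", fam$family_id),
      gene_id = fam$gene_id,
      strain_id = unname(gene_map[fam$gene_id])
    )
  })
  dplyr::bind_rows(out)
}

#' Gene-family by strain count matrix
#'
#' @param families Tibble with columns `family_id`, `gene_id` (and
#'   optionally `strain_id`, ignored in favour of `gene_map`).
#' @param gene_map Named character vector gene id -> strain id.
#' @param strains Optional character vector fixing the column set/order;
#'   defaults to the sorted strains observed in the map.
#' @return Integer matrix, rows = family ids, columns = strain ids,
#'   cell = number of that family's member genes in that strain (paralogs
#'   count individually).
#' @export
build_pan_matrix <- function(families, gene_map, strains = NULL) {
  stopifnot(all(c("family_id", "gene_id") %in% names(families)))
  unmapped <- setdiff(families$gene_id, names(gene_map))
  if (length(unmapped)) {
    stop("gene(s) not in gene map: ", paste(utils::head(unmapped, 5), collapse = ", "))
  }
  if (is.null(strains)) strains <- sort(unique(unname(gene_map[families$gene_id])))
  fam_ids <- sort(unique(families$family_id))
  pan <- matrix(0L, length(fam_ids), length(strains),
                dimnames = list(fam_ids, strains))
  if (nrow(families)) {
    tab <- table(factor(families$family_id, levels = fam_ids),
                 factor(unname(gene_map[families$gene_id]), levels = strains))
    pan[] <- as.integer(tab)
  }
  pan
}

#' Partition gene families into core, accessory and singleton
#'
#' A family is a singleton if present in exactly one strain; core if present
#' in at least `core_frac` of the strains (exact ratio, no rounding — with
#' 20 strains, presence in 19 is core at the default 0.95); accessory
#' otherwise (present in at least two strains but in fewer than the core
#' fraction). Per-strain region gene sets are materialized: `core` and
#' `accessory` hold the strain's genes in families so labelled; `whole`
#' holds all of the strain's genes, including singletons by default.
#'
#' @param pan Pan-matrix from [build_pan_matrix()] (one pan-genome group).
#' @param families Tibble `family_id`, `gene_id` restricted to the same
#'   group.
#' @param gene_map Named character vector gene id -> strain id.
#' @param core_frac Core presence threshold in (0, 1], default 0.95.
#' @param whole_includes_singletons Whether the `whole` region keeps
#'   singleton genes (default `TRUE`: the whole genome means all genes).
#' @return A `region_partition` object: list with `family_label` (tibble
#'   `family_id`, `label`, `presence`, `n_strains`) and `genes` (tibble
#'   `strain_id`, `region`, `gene_id`).
#' @export
partition_core_accessory <- function(pan, families, gene_map,
                                     core_frac = 0.95,
                                     whole_includes_singletons = TRUE) {
  if (core_frac <= 0 || core_frac > 1) stop("core_frac must be in (0, 1]")
  if (ncol(pan) < 1L) stop("pan matrix has no strains")
  n_strains <- ncol(pan)
  presence <- rowSums(pan > 0)
  label <- ifelse(presence <= 1L, "singleton",
                  ifelse(presence / n_strains >= core_frac, "core", "accessory"))
  family_label <- tibble::tibble(
    family_id = rownames(pan),
    label = unname(label),
    presence = as.integer(unname(presence)),
    n_strains = n_strains
  )
  fam_of_gene <- stats::setNames(families$family_id, families$gene_id)
  gene_label <- stats::setNames(label[match(fam_of_gene, rownames(pan))],
                                names(fam_of_gene))
  gene_strain <- gene_map[names(gene_label)]
  core_acc <- tibble::tibble(
    strain_id = unname(gene_strain),
    region = unname(gene_label),
    gene_id = names(gene_label)
  )
  core_acc <- core_acc[core_acc$region %in% c("core", "accessory"), ]
  whole_ids <- if (whole_includes_singletons) names(gene_label) else core_acc$gene_id
  whole <- tibble::tibble(
    strain_id = unname(gene_map[whole_ids]),
    region = "whole",
    gene_id = whole_ids
  )
  genes <- dplyr::bind_rows(core_acc, whole)
  genes <- genes[order(genes$strain_id, genes$region, genes$gene_id), ]
  structure(
    list(family_label = family_label[order(family_label$family_id), ],
         genes = genes, core_frac = core_frac,
         whole_includes_singletons = whole_includes_singletons),
    class = "region_partition"
  )
}

#' Combine per-group region partitions
#'
#' @param parts List of `region_partition` objects (one per pan-genome
#'   group).
#' @return A single `region_partition` with the tables row-bound.
#' @export
combine_partitions <- function(parts) {
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "region_partition")))
  structure(
    list(family_label = dplyr::bind_rows(lapply(parts, `[[`, "family_label")),
         genes = dplyr::bind_rows(lapply(parts, `[[`, "genes")),
         core_frac = parts[[1]]$core_frac,
         whole_includes_singletons = parts[[1]]$whole_includes_singletons),
    class = "region_partition"
  )
}

#' Per-strain core genome fraction
#'
#' Fraction of a strain's coding nucleotides (whole-gene set) that sits in
#' core gene families.
#'
#' @param partition A `region_partition`.
#' @param gene_lengths Named integer vector of nucleotide gene lengths.
#' @param strains Optional subset of strains; defaults to all strains in the
#'   partition.
#' @return Named numeric vector in [0, 1], one value per strain.
#' @export
core_fraction <- function(partition, gene_lengths, strains = NULL) {
  stopifnot(inherits(partition, "region_partition"))
  g <- partition$genes
  if (is.null(strains)) strains <- sort(unique(g$strain_id))
  missing_len <- setdiff(g$gene_id, names(gene_lengths))
  if (length(missing_len)) {
    stop("gene length missing for: ", paste(utils::head(missing_len, 5), collapse = ", "))
  }
  vapply(strains, function(s) {
    whole <- g$gene_id[g$strain_id == s & g$region == "whole"]
    core <- g$gene_id[g$strain_id == s & g$region == "core"]
    if (length(whole) == 0L) stop("strain with zero genes: ", s)
    sum(gene_lengths[core]) / sum(gene_lengths[whole])
  }, numeric(1))
}

#' @method print region_partition
#' @export
print.region_partition <- function(x, ...) {
  tab <- table(x$family_label$label)
  cat("Region partition:", nrow(x$family_label), "families over",
      x$family_label$n_strains[1], "strains\n")
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}
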