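# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (O(n^3) clustering, character-level k-mer
# counting, explicit window enumeration) and share no code with the package.

# Naive agglomerative complete linkage: repeatedly merge the cluster pair
# with the smallest maximum inter-member distance while that height is
# strictly below the threshold. Returns a canonical partition: list of
# sorted member vectors, ordered by first member.
oracle_complete_linkage <- function(d, threshold) {
  clusters <- as.list(rownames(d))
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best_h <- Inf
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    if (best_h >= threshold) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, character(1), 1L))]
}

# Canonical partition from the package's families tibble, for comparison.
families_as_partition <- function(fam) {
  out <- lapply(split(fam$gene_id, fam$family_id), sort)
  unname(out[order(vapply(out, `[`, character(1), 1L))])
}

# Random score table over n genes satisfying the scorer contract
# b(A;A) >= b(A;B): self scores positive, each ordered cross score drawn
# below the query's self score; a fraction of cross pairs is missing.
random_score_table <- function(n, p_missing = 0.3) {
  ids <- sprintf("g%02d", seq_len(n))
  self <- stats::runif(n, 50, 200)
  rows <- data.frame(query = ids, subject = ids, score = self)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || stats::runif(1) < p_missing) next
      rows <- rbind(rows, data.frame(query = ids[i], subject = ids[j],
                                     score = stats::runif(1, 0, self[i])))
    }
  }
  new_pair_scores(rows)
}

# Character-level trinucleotide KL divergence, counting k-mers by explicit
# substring extraction per gene.
oracle_relative_entropy <- function(seqs) {
  tri <- character(0)
  mono <- character(0)
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    mono <- c(mono, ch[ch %in% c("A", "C", "G", "T")])
    if (nchar(s) >= 3) {
      for (i in seq_len(nchar(s) - 2)) {
        w <- substr(s, i, i + 2)
        if (!grepl("[^ACGT]", w)) tri <- c(tri, w)
      }
    }
  }
  f_tri <- table(tri) / length(tri)
  f_mono <- table(mono) / length(mono)
  d <- 0
  for (w in names(f_tri)) {
    b <- strsplit(w, "")[[1]]
    d <- d + f_tri[[w]] * log(f_tri[[w]] / prod(f_mono[b]))
  }
  d
}

# GCVAR by explicit non-overlapping chunking (step == window).
oracle_gcvar_chunked <- function(seqs, window) {
  all_gc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
  }
  overall <- {
    ch <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
  }
  devs <- numeric(0)
  for (s in seqs) {
    if (nchar(s) < window) next
    starts <- seq(1, nchar(s) - window + 1, by = window)
    for (st in starts) {
      devs <- c(devs, abs(all_gc(substr(s, st, st + window - 1)) - overall))
    }
  }
  log(mean(devs))
}

# Random i.i.d. nucleotide string at a given GC.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tiny deterministic pan-matrix with a planted presence count for one
# family over n strains (other families fill the matrix).
planted_pan <- function(n_strains, presence) {
  strains <- sprintf("s%02d", seq_len(n_strains))
  pan <- matrix(0L, 2L, n_strains, dimnames = list(c("Ftest", "Fall"), strains))
  pan["Ftest", seq_len(presence)] <- 1L
  pan["Fall", ] <- 1L
  pan
}

# families/gene-map pair matching planted_pan().
planted_families <- function(n_strains, presence) {
  strains <- sprintf("s%02d", seq_len(n_strains))
  genes_test <- sprintf("%s_gT", strains[seq_len(presence)])
  genes_all <- sprintf("%s_gA", strains)
  fam <- tibble::tibble(
    family_id = c(rep("Ftest", presence), rep("Fall", n_strains)),
    gene_id = c(genes_test, genes_all)
  )
  gene_map <- stats::setNames(c(strains[seq_len(presence)], strains),
                              c(genes_test, genes_all))
  list(families = fam, gene_map = gene_map)
}
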