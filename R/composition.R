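# Base-composition statistics per (strain, region): GC content, GCVAR
# (sliding-window GC heterogeneity) and trinucleotide relative entropy.
# All three pool over the genes of a region but never let windows or
# k-mers span gene junctions, which are artifacts of concatenation.

.as_dna <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (any(!nzchar(seqs))) stop("empty sequence in region set")
  Biostrings::DNAStringSet(toupper(seqs))
}

#' GC content of a set of sequences
#'
#' Same-strand G+C count divided by the count of unambiguous bases, pooled
#' over all sequences. IUPAC ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param seqs Character vector of nucleotide sequences (one per gene).
#' @return GC fraction in [0, 1].
#' @export
gc_content <- function(seqs) {
  x <- .as_dna(seqs)
  counts <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"),
                                                     drop = FALSE])
  total <- sum(counts)
  if (total == 0) stop("no unambiguous bases in input")
  unname((counts["G"] + counts["C"]) / total)
}

#' Trinucleotide relative entropy of a set of sequences
#'
#' Kullback-Leibler divergence between observed overlapping trinucleotide
#' frequencies and the frequencies expected from the pooled mononucleotide
#' frequencies:
#' \deqn{D = \sum_{XYZ} f_{XYZ} \log\frac{f_{XYZ}}{f_X f_Y f_Z}}
#' Trinucleotides are counted with step 1 within each gene (never across
#' gene junctions) and pooled; windows containing non-ACGT codes are
#' skipped. Mononucleotide frequencies come from the same pooled sequences.
#' Zero-count trinucleotides contribute 0. High values mean biased
#' oligonucleotide usage; an i.i.d. sequence tends to 0 with length.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param log_base Base of the logarithm; `exp(1)` (nats, default) or 2.
#' @return Non-negative relative entropy.
#' @export
relative_entropy <- function(seqs, log_base = exp(1)) {
  x <- .as_dna(seqs)
  tri <- colSums(Biostrings::trinucleotideFrequency(x, step = 1))
  n_tri <- sum(tri)
  if (n_tri == 0) stop("no valid trinucleotide windows (need pooled length >= 3)")
  mono <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"),
                                                   drop = FALSE])
  f_mono <- mono / sum(mono)
  f_tri <- tri / n_tri
  bases <- strsplit(names(f_tri), "")
  f_exp <- vapply(bases, function(b) prod(f_mono[b]), numeric(1))
  pos <- f_tri > 0
  sum(f_tri[pos] * log(f_tri[pos] / f_exp[pos], base = log_base))
}

#' GCVAR: within-region GC content variation
#'
#' The log of the mean absolute deviation between sliding-window GC content
#' and the region's overall GC content:
#' \deqn{GCVAR = \log\left(\frac{1}{N}\sum_{i=1}^{N} |D_i|\right),\quad
#'   D_i = GC_i - GC}
#' Windows of `window` bp advance by `step` within each gene and never span
#' gene junctions; genes shorter than the window are skipped for windowing
#' (they still contribute to the overall GC). Window GC excludes ambiguous
#' bases like [gc_content()]. If every window matches the overall GC
#' exactly, the mean deviation is 0 and `-Inf` is returned with attribute
#' `zero_deviation = TRUE`.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param window Window width in bp (default 100).
#' @param step Window step in bp (default 1, i.e. sliding).
#' @param log_base Base of the logarithm; `exp(1)` (nats, default) or 2.
#' @return GCVAR value (possibly `-Inf`).
#' @export
gcvar <- function(seqs, window = 100L, step = 1L, log_base = exp(1)) {
  stopifnot(window >= 2L, step >= 1L)
  x <- .as_dna(seqs)
  lens <- Biostrings::width(x)
  if (all(lens < window)) stop("no sequence reaches the window length")
  overall <- gc_content(seqs)
  devs <- lapply(which(lens >= window), function(i) {
    s <- x[[i]]
    gc_cnt <- Biostrings::letterFrequencyInSlidingView(s, window, "GC")[, 1]
    at_cnt <- Biostrings::letterFrequencyInSlidingView(s, window, "AT")[, 1]
    idx <- seq(1L, length(gc_cnt), by = step)
    gc_cnt <- gc_cnt[idx]; at_cnt <- at_cnt[idx]
    ok <- (gc_cnt + at_cnt) > 0
    abs(gc_cnt[ok] / (gc_cnt[ok] + at_cnt[ok]) - overall)
  })
  devs <- unlist(devs)
  if (length(devs) == 0L) stop("no valid windows")
  m <- mean(devs)
  out <- log(m, base = log_base)
  attr(out, "zero_deviation") <- (m == 0)
  out
}

#' Composition table: one row per strain and region
#'
#' Applies [gc_content()], [gcvar()] and [relative_entropy()] to the core,
#' accessory and whole gene sets of every strain in a region partition.
#' Regions with no genes are emitted with `NA` statistics and flagged, as
#' are zero-deviation GCVAR rows.
#'
#' @param partition A `region_partition` from [partition_core_accessory()].
#' @param genes Tibble with columns `gene_id`, `nt_seq` (or a named
#'   character vector of nucleotide sequences).
#' @param window,step,log_base Passed to [gcvar()] / [relative_entropy()].
#' @return Tibble with columns `strain_id`, `region`, `n_genes`,
#'   `total_len`, `gc`, `gcvar`, `rel_entropy`, `flags`.
#' @export
composition_table <- function(partition, genes, window = 100L, step = 1L,
                              log_base = exp(1)) {
  stopifnot(inherits(partition, "region_partition"))
  seqs <- if (is.character(genes)) genes else {
    stats::setNames(genes$nt_seq, genes$gene_id)
  }
  part_genes <- partition$genes
  missing <- setdiff(part_genes$gene_id, names(seqs))
  if (length(missing)) {
    stop("nucleotide sequence missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  strains <- sort(unique(part_genes$strain_id))
  grid <- expand.grid(strain_id = strains,
                      region = c("core", "accessory", "whole"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$strain_id, grid$region), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ids <- part_genes$gene_id[part_genes$strain_id == grid$strain_id[i] &
                              part_genes$region == grid$region[i]]
    flags <- character(0)
    if (length(ids) == 0L) {
      return(tibble::tibble(strain_id = grid$strain_id[i],
                            region = grid$region[i], n_genes = 0L,
                            total_len = 0L, gc = NA_real_, gcvar = NA_real_,
                            rel_entropy = NA_real_, flags = "empty_region"))
    }
    ss <- seqs[ids]
    gv <- tryCatch(gcvar(ss, window = window, step = step, log_base = log_base),
                   error = function(e) {
                     flags <<- c(flags, "no_window"); NA_real_
                   })
    if (isTRUE(attr(gv, "zero_deviation"))) flags <- c(flags, "zero_deviation")
    tibble::tibble(
      strain_id = grid$strain_id[i], region = grid$region[i],
      n_genes = length(ids), total_len = sum(nchar(ss)),
      gc = gc_content(ss),
      gcvar = as.numeric(gv),
      rel_entropy = relative_entropy(ss, log_base = log_base),
      flags = if (length(flags)) paste(flags, collapse = ";") else ""
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "log_base") <- log_base
  out
}
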