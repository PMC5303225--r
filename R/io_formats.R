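# Readers and writers for the external formats the pipeline touches:
# FASTA (nucleotide and protein), BLAST tabular (outfmt 6), Newick trees,
# and the TSV tables (gene-to-strain map, strain metadata).

#' Read a FASTA file into a named character vector
#'
#' Sequence identifiers are taken from the first whitespace-delimited token
#' of each header line. Sequences are upper-cased and returned in file order.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"nt"` (nucleotide) or `"aa"` (amino acid);
#'   controls which residue codes are considered legal.
#' @param strict If `TRUE`, any character outside the strict alphabet
#'   (`ACGT` for nucleotide, the 20 standard residues for protein) is an
#'   error; otherwise IUPAC ambiguity codes are accepted and a warning lists
#'   the sequences that carry them.
#' @return Named character vector of upper-case sequences, one per record.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa"), strict = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty sequence(s) in ", path)
  legal <- if (alphabet == "nt") {
    if (strict) "ACGT" else paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  } else {
    if (strict) "ACDEFGHIKLMNPQRSTVWY" else "ACDEFGHIKLMNPQRSTVWYBJZXUO*"
  }
  bad <- grepl(sprintf("[^%s]", legal), seqs)
  if (any(bad)) {
    msg <- paste0("sequences with characters outside the ", alphabet,
                  " alphabet: ", paste(utils::head(ids[bad], 5), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate coding sequences under the bacterial genetic code
#'
#' Translates in-frame coding sequences with translation table 11
#' (bacterial/archaeal) by default. A terminal stop codon is dropped from
#' the protein; internal stops are kept as `*` and reported with a warning.
#'
#' @param nt_seq Character vector of nucleotide coding sequences.
#' @param table NCBI genetic code id (default `"11"`).
#' @param strict If `TRUE`, a length not divisible by 3 is an error;
#'   otherwise the trailing partial codon is truncated with a warning.
#' @return Character vector of protein sequences. Sequences that contained
#'   an internal stop are listed in the `internal_stops` attribute.
#' @export
translate_cds <- function(nt_seq, table = "11", strict = FALSE) {
  stopifnot(is.character(nt_seq), length(nt_seq) >= 1L)
  rem <- nchar(nt_seq) %% 3L
  if (any(rem != 0L)) {
    msg <- paste0(sum(rem != 0L), " sequence(s) with length not divisible by 3")
    if (strict) stop(msg)
    warning(msg, "; trailing partial codons truncated")
    nt_seq <- substr(nt_seq, 1L, nchar(nt_seq) - rem)
  }
  code <- Biostrings::getGeneticCode(table)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt_seq),
    genetic.code = code, if.fuzzy.codon = "solve"
  ))
  aa <- sub("\\*$", "", aa)
  internal <- grepl("\\*", aa)
  if (any(internal)) {
    warning(sum(internal), " sequence(s) contain internal stop codons")
  }
  names(aa) <- names(nt_seq)
  attr(aa, "internal_stops") <- which(internal)
  aa
}

#' Read all-vs-all similarity scores in BLAST tabular format
#'
#' Expects 12-column `outfmt 6` lines with the query id in column 1, the
#' subject id in column 2 and the bitscore in column 12. When a
#' (query, subject) pair occurs more than once (multiple HSPs), the maximum
#' bitscore is kept, so the result holds one score per ordered pair.
#'
#' @param path Path to the tabular file.
#' @return A `pair_scores` tibble with columns `query`, `subject`, `score`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BLAST tabular file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("malformed BLAST tabular line(s) (expected 12 columns): line ",
         paste(utils::head(which(nf != 12L), 5), collapse = ", "))
  }
  q <- vapply(fields, `[[`, character(1), 1L)
  s <- vapply(fields, `[[`, character(1), 2L)
  b <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 12L)))
  if (anyNA(b)) {
    stop("non-numeric bitscore at line ",
         paste(utils::head(which(is.na(b)), 5), collapse = ", "))
  }
  df <- data.frame(query = q, subject = s, score = b)
  agg <- stats::aggregate(score ~ query + subject, data = df, FUN = max)
  new_pair_scores(agg[order(agg$query, agg$subject), , drop = FALSE])
}

#' Construct a pair-scores table
#'
#' @param df Data frame with columns `query`, `subject`, `score`.
#' @param scorer Label recording where the scores came from (`"import"` or
#'   `"smith-waterman"`); mixing the two in one analysis is not allowed.
#' @return A `pair_scores` tibble.
#' @export
new_pair_scores <- function(df, scorer = "import") {
  stopifnot(all(c("query", "subject", "score") %in% names(df)))
  if (any(df$score < 0)) stop("negative similarity scores are not allowed")
  out <- tibble::as_tibble(df[c("query", "subject", "score")])
  class(out) <- c("pair_scores", class(out))
  attr(out, "scorer") <- scorer
  out
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @param require_lengths If `TRUE` (default), missing branch lengths are an
#'   error, since the phylogenetic regression needs them.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path, require_lengths = TRUE) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick file: ", path))
  if (is.null(tree)) stop("unparseable Newick file: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (require_lengths) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  }
  tree
}

#' Read the two-column gene-to-strain map
#'
#' @param path TSV with header columns `gene_id` and `strain_id`.
#' @return Named character vector mapping gene id to strain id.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("gene_id", "strain_id") %in% names(df))) {
    stop("gene map must have columns gene_id and strain_id")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene map")
  stats::setNames(df$strain_id, df$gene_id)
}

#' Read the strain metadata table
#'
#' @param path TSV with header columns `strain_id`, `species`, `genus`,
#'   `phylum`.
#' @return Tibble of strain metadata with one row per strain.
#' @export
read_strain_meta <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("strain_id", "species", "genus", "phylum")
  if (!all(need %in% names(df))) {
    stop("strain metadata must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$strain_id)) stop("duplicate strain_id in metadata")
  if (any(!nzchar(as.matrix(df[need])))) stop("empty fields in strain metadata")
  tibble::as_tibble(df[need])
}

#' Check cross-references between genes, map and metadata
#'
#' Every gene must map to a strain and every mapped strain must appear in
#' the metadata exactly once.
#'
#' @param gene_ids Character vector of gene ids.
#' @param gene_map Named character vector from [read_gene_map()].
#' @param meta Strain metadata tibble from [read_strain_meta()].
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validate_cross_refs <- function(gene_ids, gene_map, meta) {
  missing_genes <- setdiff(gene_ids, names(gene_map))
  if (length(missing_genes)) {
    stop("genes missing from gene map: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  missing_strains <- setdiff(unique(gene_map[gene_ids]), meta$strain_id)
  if (length(missing_strains)) {
    stop("strains missing from metadata: ",
         paste(utils::head(missing_strains, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# Canonical TSV writer: fixed numeric formatting so identical inputs give
# byte-identical artifacts.
write_tsv_canonical <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
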