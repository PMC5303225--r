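# End-to-end orchestration: cluster -> partition -> compose -> model,
# with TSV artifacts, simple figures and a manifest. All analysis stages
# are deterministic; randomness is confined to the synthetic generator.

#' Build a validated run configuration
#'
#' Defaults follow the analysis definition: complete-linkage cut 0.75,
#' core presence threshold 0.95, 100 bp sliding windows with step 1,
#' natural logarithms, species-level pan-genomes.
#'
#' @param out_dir Output directory for artifacts.
#' @param sim A `sim_spec` to generate inputs, or `NULL` to read files.
#' @param cds,proteins,gene_map,meta,scores,tree Input paths (used when
#'   `sim` is `NULL`); `proteins` and `scores` are optional (`proteins`
#'   falls back to internal translation, `scores` to the internal aligner),
#'   `tree` enables the phylogenetic GLS stage.
#' @param threshold Complete-linkage BLAST-distance cut.
#' @param core_frac Core presence threshold.
#' @param window,step GCVAR sliding-window parameters (bp).
#' @param log_base `"e"` or `"2"` for GCVAR and relative entropy.
#' @param level Pan-genome grouping level, `"species"` or `"genus"`.
#' @param whole_includes_singletons Whether whole-genome statistics include
#'   singleton genes.
#' @param seed Integer seed (only the simulation consumes randomness).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, sim = NULL, cds = NULL, proteins = NULL,
                       gene_map = NULL, meta = NULL, scores = NULL,
                       tree = NULL, threshold = 0.75, core_frac = 0.95,
                       window = 100L, step = 1L, log_base = c("e", "2"),
                       level = c("species", "genus"),
                       whole_includes_singletons = TRUE, seed = 42L) {
  log_base <- match.arg(log_base)
  level <- match.arg(level)
  if (is.null(sim) && (is.null(cds) || is.null(gene_map) || is.null(meta))) {
    stop("either 'sim' or the input paths cds/gene_map/meta are required")
  }
  if (!is.null(sim) && !inherits(sim, "sim_spec")) {
    stop("'sim' must be a sim_spec object")
  }
  structure(
    list(out_dir = out_dir, sim = sim, cds = cds, proteins = proteins,
         gene_map = gene_map, meta = meta, scores = scores, tree = tree,
         threshold = threshold, core_frac = core_frac,
         window = as.integer(window), step = as.integer(step),
         log_base = log_base, level = level,
         whole_includes_singletons = whole_includes_singletons,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim` mapping
#' is passed to [sim_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_spec, raw$sim)
  do.call(run_config, raw)
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes cluster, partition, compose and model stages and writes
#' families, pan-matrix, partition, composition, model summaries, Tukey
#' contrasts, sign summary, core fractions and box/scatter figures to the
#' output directory, together with a manifest (config hash, seed, artifact
#' checksums). Reruns with an identical configuration and seed produce
#' byte-identical TSV artifacts.
#'
#' @param config A `run_config`.
#' @return List with all intermediate objects, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_base <- if (config$log_base == "e") exp(1) else 2

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    .stage_msg("input", "simulating pan-genome (seed ", config$sim$seed, ")")
    sim <- simulate_pangenome(config$sim)
    genes <- sim$genes
    meta <- sim$meta
    tree <- sim$tree
  } else {
    .stage_msg("input", "reading ", config$cds)
    nt <- read_fasta(config$cds, "nt")
    aa <- if (!is.null(config$proteins)) {
      read_fasta(config$proteins, "aa")
    } else {
      translate_cds(nt)
    }
    if (!setequal(names(nt), names(aa))) {
      stop("[input] nucleotide and protein FASTA ids do not match")
    }
    gmap <- read_gene_map(config$gene_map)
    genes <- tibble::tibble(gene_id = names(nt),
                            strain_id = unname(gmap[names(nt)]),
                            nt_seq = unname(nt),
                            aa_seq = unname(aa[names(nt)]))
    meta <- read_strain_meta(config$meta)
    tree <- if (!is.null(config$tree)) read_newick(config$tree) else NULL
  }
  gene_map <- stats::setNames(genes$strain_id, genes$gene_id)
  validate_cross_refs(genes$gene_id, gene_map, meta)
  .stage_msg("input", nrow(genes), " genes, ", nrow(meta), " strains")

  # --- cluster --------------------------------------------------------
  scores <- if (!is.null(config$scores)) read_blast_tabular(config$scores)
  proteins <- stats::setNames(genes$aa_seq, genes$gene_id)
  families <- cluster_pangenome(proteins, gene_map, meta,
                                level = config$level, scores = scores,
                                threshold = config$threshold)
  .stage_msg("cluster", length(unique(families$family_id)), " families in ",
             length(unique(families$group)), " pan-genome group(s)")

  # --- partition ------------------------------------------------------
  parts <- lapply(sort(unique(families$group)), function(g) {
    fg <- families[families$group == g, ]
    strains <- meta$strain_id[meta[[config$level]] == g]
    pan <- build_pan_matrix(fg, gene_map, strains = strains)
    partition_core_accessory(
      pan, fg, gene_map, core_frac = config$core_frac,
      whole_includes_singletons = config$whole_includes_singletons
    )
  })
  partition <- combine_partitions(parts)
  lab <- table(partition$family_label$label)
  .stage_msg("partition", paste(names(lab), as.integer(lab), sep = "=",
                                collapse = ", "))

  # --- compose --------------------------------------------------------
  comp <- composition_table(partition, genes, window = config$window,
                            step = config$step, log_base = log_base)
  comp_meta <- dplyr::inner_join(comp, meta, by = "strain_id")
  .stage_msg("compose", nrow(comp), " strain-region rows")

  # --- model ----------------------------------------------------------
  responses <- c("gc", "rel_entropy", "gcvar")
  models <- list()
  tukeys <- list()
  for (resp in responses) {
    m <- tryCatch(
      fit_mixed_model(comp_meta, response = resp, fixed = "region"),
      error = function(e) {
        .stage_msg("model", "skipping ", resp, ": ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(m)) next
    models[[resp]] <- m
    tukeys[[resp]] <- dplyr::mutate(tukey_hsd(m), response = resp,
                                    .before = 1)
  }
  signs <- per_strain_sign_summary(comp)
  lens <- stats::setNames(nchar(genes$nt_seq), genes$gene_id)
  core_fr <- core_fraction(partition, lens)
  pgls <- NULL
  if (!is.null(tree)) {
    sp_tab <- comp_meta |>
      dplyr::filter(.data$region == "whole", is.finite(.data$gc)) |>
      dplyr::group_by(.data$species, .data$phylum) |>
      dplyr::summarise(gc = mean(.data$gc), .groups = "drop")
    if (length(unique(sp_tab$phylum)) >= 2L &&
        setequal(tree$tip.label, sp_tab$species)) {
      pgls <- fit_pgls(sp_tab, tree)
      .stage_msg("model", "PGLS lambda = ", round(pgls$lambda, 3),
                 ", phylum p = ", format.pval(pgls$p_predictor))
    } else {
      .stage_msg("model", "skipping PGLS (tree/metadata mismatch or <2 phyla)")
    }
  }

  # --- report ---------------------------------------------------------
  out <- config$out_dir
  write_tsv_canonical(families, file.path(out, "families.tsv"))
  pan_long <- dplyr::count(families, .data$group, .data$family_id,
                           .data$strain_id, name = "n_genes")
  write_tsv_canonical(pan_long, file.path(out, "pan_matrix.tsv"))
  write_tsv_canonical(partition$family_label, file.path(out, "partition.tsv"))
  write_tsv_canonical(comp, file.path(out, "composition.tsv"))
  model_summary <- dplyr::bind_rows(lapply(names(models), function(resp) {
    m <- models[[resp]]
    tibble::tibble(response = resp, term = names(m$beta),
                   estimate = unname(m$beta), se = unname(m$se),
                   df = unname(m$df), p = unname(m$p),
                   singular = m$singular, n_obs = m$n_obs)
  }))
  write_tsv_canonical(model_summary, file.path(out, "model_summary.tsv"))
  write_tsv_canonical(dplyr::bind_rows(tukeys), file.path(out, "tukey.tsv"))
  write_tsv_canonical(signs, file.path(out, "sign_summary.tsv"))
  write_tsv_canonical(
    tibble::tibble(strain_id = names(core_fr), core_fraction = core_fr),
    file.path(out, "core_fraction.tsv")
  )
  if (!is.null(pgls)) {
    write_tsv_canonical(
      tibble::tibble(lambda = pgls$lambda, loglik = pgls$loglik,
                     p_lambda = pgls$p_lambda, p_phylum = pgls$p_predictor),
      file.path(out, "pgls.tsv")
    )
  }
  for (resp in names(models)) {
    p <- plot_region_boxplot(comp, resp)
    ggplot2::ggsave(file.path(out, paste0("boxplot_", resp, ".png")), p,
                    width = 6, height = 4, dpi = 120)
  }
  ggplot2::ggsave(file.path(out, "core_accessory_gc.png"),
                  plot_core_accessory_gc(comp), width = 6, height = 4,
                  dpi = 120)
  manifest <- .write_manifest(config, out)
  .stage_msg("report", "artifacts written to ", out)
  invisible(list(genes = genes, meta = meta, tree = tree,
                 families = families, partition = partition,
                 composition = comp, models = models,
                 tukey = dplyr::bind_rows(tukeys), signs = signs,
                 core_fraction = core_fr, pgls = pgls, manifest = manifest))
}

.write_manifest <- function(config, out) {
  cfg <- config
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null",
                               digits = NA)
  cfg_path <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_path)
  tsvs <- sort(list.files(out, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    artifacts = lapply(stats::setNames(tsvs, basename(tsvs)),
                       function(f) unname(tools::md5sum(f)))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "manifest.json"))
  manifest
}

#' Count strains whose core statistic exceeds the whole-genome statistic
#'
#' For each statistic, counts the strains whose core-region value is on the
#' expected side of the whole-genome value: above for GC content and
#' relative entropy, below for GCVAR. Strains missing a finite core or
#' whole value for a statistic are skipped and reported.
#'
#' @param comp Composition table from [composition_table()].
#' @return Tibble with `statistic`, `direction`, `count`,
#'   `n_strains_compared`, `n_skipped`.
#' @export
per_strain_sign_summary <- function(comp) {
  wide <- comp |>
    dplyr::select(dplyr::all_of(c("strain_id", "region", "gc", "gcvar",
                                  "rel_entropy"))) |>
    tidyr::pivot_wider(names_from = "region",
                       values_from = c("gc", "gcvar", "rel_entropy"))
  spec <- list(gc = ">", rel_entropy = ">", gcvar = "<")
  rows <- lapply(names(spec), function(stat) {
    a <- wide[[paste0(stat, "_core")]]
    b <- wide[[paste0(stat, "_whole")]]
    ok <- is.finite(a) & is.finite(b)
    cmp <- if (spec[[stat]] == ">") a[ok] > b[ok] else a[ok] < b[ok]
    tibble::tibble(
      statistic = stat,
      direction = paste("core", spec[[stat]], "whole"),
      count = sum(cmp),
      n_strains_compared = sum(ok),
      n_skipped = sum(!ok)
    )
  })
  dplyr::bind_rows(rows)
}

#' Box plot of a composition statistic by region
#'
#' @param comp Composition table.
#' @param stat Column to plot: `"gc"`, `"gcvar"` or `"rel_entropy"`.
#' @return A ggplot object.
#' @export
plot_region_boxplot <- function(comp, stat = c("gc", "gcvar", "rel_entropy")) {
  stat <- match.arg(stat)
  df <- comp[is.finite(comp[[stat]]), ]
  df$region <- factor(df$region, levels = c("accessory", "whole", "core"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data[[stat]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "region", y = stat) +
    ggplot2::theme_minimal()
}

#' Scatter of core/accessory GC ratio against whole-genome GC
#'
#' Plots the log2 ratio of core to accessory GC content per strain against
#' its whole-genome GC content.
#'
#' @param comp Composition table.
#' @return A ggplot object.
#' @export
plot_core_accessory_gc <- function(comp) {
  wide <- comp |>
    dplyr::select(dplyr::all_of(c("strain_id", "region", "gc"))) |>
    tidyr::pivot_wider(names_from = "region", values_from = "gc")
  wide <- wide[is.finite(wide$core) & is.finite(wide$accessory) &
                 is.finite(wide$whole), ]
  wide$log2_ratio <- log2(wide$core / wide$accessory)
  ggplot2::ggplot(wide, ggplot2::aes(x = 100 * .data$whole,
                                     y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "whole-genome GC (%)",
                  y = "log2(core GC / accessory GC)") +
    ggplot2::theme_minimal()
}
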