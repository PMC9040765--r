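#' @title End-to-end pipeline run
#'
#' @description
#' One call reads the five input tables, runs novelty classification,
#' capability calling, lineage-level pathway inference and transcript
#' aggregation, and writes a TSV report bundle. Each stage is equally
#' usable on its own; `run_pipeline()` exists so a whole analysis is one
#' deterministic, replayable step.
#'
#' @name pipeline
NULL

#' Assemble a pipeline run configuration
#'
#' @param genome_table,ref_counts,gene_hits,ko_table,tpm_table input TSV
#'   paths. `tpm_table` and `ko_table` may be `NULL` to skip those stages.
#' @param ruleset_path capability rule file (default: shipped rules).
#' @param pathway_path pathway definition file (default: shipped
#'   illustrative set).
#' @param out_dir report output directory.
#' @param score_threshold hit bit-score threshold (default 100).
#' @param decimals rounding decimals for report percentages.
#' @return a `run_config` list.
#' @export
run_config <- function(genome_table, ref_counts, gene_hits,
                       ko_table = NULL, tpm_table = NULL,
                       ruleset_path = default_ruleset_path(),
                       pathway_path = NULL,
                       out_dir = tempfile("sulfur_report_"),
                       score_threshold = 100, decimals = 1) {
  stopifnot(score_threshold >= 0)
  paths <- c(genome_table, ref_counts, gene_hits, ko_table, tpm_table,
             ruleset_path, pathway_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(genome_table = genome_table, ref_counts = ref_counts,
                 gene_hits = gene_hits, ko_table = ko_table,
                 tpm_table = tpm_table, ruleset_path = ruleset_path,
                 pathway_path = pathway_path, out_dir = out_dir,
                 score_threshold = score_threshold, decimals = decimals),
            class = "run_config")
}

#' Run the full pipeline and write the report bundle
#'
#' Stages: (1) genome admission and family-rank novelty summary per
#' habitat; (2) water/sediment family sharing; (3) capability calls and
#' habitat summaries; (4) lineage grouping and pathway matrix (when a KO
#' table is given); (5) TPM aggregation (when an abundance table is
#' given). Every output table carries a provenance comment line (package
#' version and rule-set checksum). Rerunning on the same inputs gives
#' byte-identical tables.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all in-memory results and the written
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prov <- paste0(
    "sulfurMAGs ", as.character(utils::packageVersion("sulfurMAGs")),
    " ruleset_md5=", unname(tools::md5sum(config$ruleset_path)),
    " threshold=", config$score_threshold)
  out <- list()
  paths <- character(0)

  genomes <- read_genome_table(config$genome_table)
  ref <- read_reference_counts(config$ref_counts)
  habitats <- intersect(c("sediment", "water"), unique(genomes$habitat))

  nov <- do.call(rbind, lapply(habitats, function(h) {
    s <- novelty_summary(genomes[genomes$habitat == h, ], ref, "family")
    data.frame(habitat = h, rank = s$rank, n_genomes = s$n_genomes,
               n_genomes_novel = s$n_genomes_novel,
               n_genomes_rare = s$n_genomes_rare,
               pct_novel = s$pct_novel, pct_rare = s$pct_rare,
               pct_combined = s$pct_combined,
               n_taxa_novel = s$n_taxa_novel, n_taxa_rare = s$n_taxa_rare,
               stringsAsFactors = FALSE)
  }))
  out$novelty <- nov
  paths["novelty"] <- file.path(config$out_dir, "novelty_summary.tsv")
  write_tsv_plain(nov, paths[["novelty"]], prov)

  if (all(c("sediment", "water") %in% habitats)) {
    part <- shared_family_partition(genomes[genomes$habitat == "sediment", ],
                                    genomes[genomes$habitat == "water", ])
    out$family_partition <- part
    pdf_ <- data.frame(n_water_shared = part$n_water_shared,
                       n_water_specific = part$n_water_specific)
    paths["partition"] <- file.path(config$out_dir, "family_partition.tsv")
    write_tsv_plain(pdf_, paths[["partition"]], prov)
  } else {
    out$family_partition <- NULL
    message("only one habitat present; family-sharing section skipped")
  }

  # enrichment per order among study genomes (defined orders only)
  ord_counts <- table(genomes$order)
  enr <- data.frame(order = names(ord_counts),
                    study_count = as.integer(ord_counts),
                    stringsAsFactors = FALSE)
  enr$ref_count <- ref_count(ref, "order", enr$order)
  enr$enrichment_pct <- ifelse(
    enr$ref_count > 0,
    round_half_up(100 * enr$study_count / enr$ref_count, 2), NA_real_)
  out$enrichment <- enr
  paths["enrichment"] <- file.path(config$out_dir, "order_enrichment.tsv")
  write_tsv_plain(enr, paths[["enrichment"]], prov)

  ruleset <- load_ruleset(config$ruleset_path)
  presence <- load_hits(config$gene_hits, config$score_threshold)
  calls <- call_genomes(presence, genomes, ruleset)
  out$calls <- calls
  paths["calls"] <- file.path(config$out_dir, "capability_calls.tsv")
  write_calls(calls, paths[["calls"]], prov)

  summ <- summarize_calls(calls, genomes, config$decimals)
  out$call_summary <- summ
  paths["per_capability"] <- file.path(config$out_dir,
                                       "capability_summary.tsv")
  write_tsv_plain(summ$per_capability, paths[["per_capability"]], prov)
  paths["habitat_totals"] <- file.path(config$out_dir, "habitat_totals.tsv")
  write_tsv_plain(summ$habitat_totals, paths[["habitat_totals"]], prov)

  if (!is.null(config$ko_table)) {
    ko_sets <- load_ko_table(config$ko_table)
    groups <- build_lineage_groups(genomes)
    pathways <- if (is.null(config$pathway_path)) {
      load_pathway_defs()
    } else {
      load_pathway_defs(config$pathway_path)
    }
    m <- lineage_capability_matrix(groups, ko_sets, pathways)
    out$lineage_groups <- groups
    out$lineage_matrix <- m
    paths["lineage_matrix"] <- file.path(config$out_dir,
                                         "lineage_pathways.tsv")
    write_lineage_matrix(m, paths[["lineage_matrix"]], prov)
  }

  if (!is.null(config$tpm_table)) {
    tpm <- read_tpm_table(config$tpm_table)
    agg <- aggregate_tpm(tpm, default_gene_groups(), genomes)
    out$transcription <- agg
    paths["tpm_by_phylum"] <- file.path(config$out_dir,
                                        "tpm_group_phylum.tsv")
    write_tsv_plain(agg$by_phylum, paths[["tpm_by_phylum"]], prov)
    paths["tpm_totals"] <- file.path(config$out_dir,
                                     "tpm_group_totals.tsv")
    write_tsv_plain(agg$group_totals, paths[["tpm_totals"]], prov)
  }

  out$paths <- paths
  invisible(out)
}
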