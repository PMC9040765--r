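#' @title Lineage-level pathway presence from KO annotations
#'
#' @description
#' Genomes are grouped into lineages by a size rule — one group per order
#' for orders with 5 study genomes or less, one group per family within
#' orders with more than 5 — and a metabolic pathway is called present in a
#' lineage when at least one member genome carries at least 80% of the
#' pathway's KOs (per-genome, never pooled across members).
#'
#' @name lineage_metabolism
NULL

#' Group genomes into order- or family-level lineages
#'
#' Orders with 5 or fewer study genomes form a single order-level group;
#' orders with more than 5 are split into family-level groups. Placeholder
#' names (ZN convention) are ordinary group keys, so genomes classified
#' only above order still land in exactly one group.
#'
#' @param genomes a genome collection data frame.
#' @return data frame with columns `rank`, `taxon`, `n_genomes` and a
#'   list-column `genome_ids`; the groups partition the collection.
#' @export
build_lineage_groups <- function(genomes) {
  stopifnot(is.data.frame(genomes), nrow(genomes) > 0L)
  order_sizes <- table(genomes$order)
  rows <- list()
  for (ord in names(order_sizes)) {
    in_ord <- genomes[genomes$order == ord, , drop = FALSE]
    if (order_sizes[[ord]] <= 5L) {
      rows[[length(rows) + 1L]] <- list(rank = "order", taxon = ord,
                                        genome_ids = in_ord$genome_id)
    } else {
      for (fam in unique(in_ord$family)) {
        ids <- in_ord$genome_id[in_ord$family == fam]
        rows[[length(rows) + 1L]] <- list(rank = "family", taxon = fam,
                                          genome_ids = ids)
      }
    }
  }
  out <- data.frame(
    rank = vapply(rows, `[[`, character(1), "rank"),
    taxon = vapply(rows, `[[`, character(1), "taxon"),
    n_genomes = vapply(rows, function(r) length(r$genome_ids), integer(1)),
    stringsAsFactors = FALSE
  )
  out$genome_ids <- lapply(rows, `[[`, "genome_ids")
  key <- paste(out$rank, out$taxon)
  if (anyDuplicated(key)) {
    stop("internal error: duplicate lineage group keys", call. = FALSE)
  }
  out[order(out$rank, out$taxon), , drop = FALSE]
}

#' Load pathway definitions from a YAML file
#'
#' Each pathway entry carries `name`, `category`, an optional `threshold`
#' (fraction of KOs required, default 0.80) and a `kos` list. The shipped
#' file `system.file("extdata", "pathway_defs.yaml", package = "sulfurMAGs")`
#' is a small illustrative default with synthetic KO numbers; real analyses
#' should supply their own curated KO lists.
#'
#' @param path YAML pathway file.
#' @return named list of pathway definitions.
#' @export
load_pathway_defs <- function(path = system.file("extdata",
                                                 "pathway_defs.yaml",
                                                 package = "sulfurMAGs",
                                                 mustWork = TRUE)) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw$pathways, function(p) {
    pathway_def(p$name, p$kos, threshold = p$threshold %||% 0.80,
                category = p$category %||% "uncategorized")
  })
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

#' Define one pathway
#'
#' @param name pathway name.
#' @param kos character vector of KO ids (K#####), non-empty.
#' @param threshold required fraction of KOs in a single genome,
#'   0 < threshold <= 1 (default 0.80).
#' @param category category tag (sugars, amino acids, SCFA, ...).
#' @return a `pathway_def` list.
#' @export
pathway_def <- function(name, kos, threshold = 0.80,
                        category = "uncategorized") {
  kos <- unique(as.character(kos))
  if (length(kos) == 0L) stop("pathway '", name, "' has an empty KO set",
                              call. = FALSE)
  if (!all(grepl("^K[0-9]{5}$", kos))) {
    stop("pathway '", name, "' has non-conforming KO id(s)", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("pathway '", name, "' threshold must lie in (0, 1]", call. = FALSE)
  }
  list(name = name, kos = kos, threshold = threshold, category = category)
}

# Inclusive completeness comparison without floating error at the
# boundary: n_hit / n_ko >= threshold is tested by integer
# cross-multiplication with the threshold scaled to 6 decimals, so
# 8-of-10 passes a 0.80 threshold exactly and 79-of-100 fails.
completeness_passes <- function(n_hit, n_ko, threshold) {
  thr_num <- round(threshold * 1e6)
  n_hit * 1e6 >= thr_num * n_ko
}

#' Pathway presence in one lineage group
#'
#' Present iff the best member genome carries at least `threshold` of the
#' pathway's KOs. The completeness of each genome is
#' `|pathway KOs present| / |pathway KOs|`; the maximum over members is
#' compared inclusively against the threshold with exact arithmetic.
#' Pooling KOs across member genomes is deliberately not done.
#'
#' @param group one row of [build_lineage_groups()] output (or a list with
#'   a `genome_ids` field).
#' @param ko_sets named list `genome_id -> KO id vector` (see
#'   [load_ko_table()]).
#' @param pathway a [pathway_def()].
#' @return list: `present`, `best_genome`, `best_completeness` (fraction).
#' @export
pathway_presence <- function(group, ko_sets, pathway) {
  ids <- if (is.data.frame(group)) group$genome_ids[[1]] else group$genome_ids
  if (length(ids) == 0L) stop("empty lineage group", call. = FALSE)
  n_ko <- length(pathway$kos)
  n_hit <- vapply(ids, function(g)
    sum(pathway$kos %in% (ko_sets[[g]] %||% character(0))), integer(1))
  best <- which.max(n_hit)
  list(
    present = completeness_passes(max(n_hit), n_ko, pathway$threshold),
    best_genome = ids[best],
    best_completeness = max(n_hit) / n_ko
  )
}

#' Lineage-by-pathway presence matrix
#'
#' @param groups output of [build_lineage_groups()].
#' @param ko_sets named list `genome_id -> KO id vector`.
#' @param pathways named list of [pathway_def()]s.
#' @return logical matrix (lineages x pathways; rownames `rank:taxon`),
#'   with a per-category lineage-fraction summary in attribute
#'   `category_summary`.
#' @export
lineage_capability_matrix <- function(groups, ko_sets, pathways) {
  m <- matrix(FALSE, nrow = nrow(groups), ncol = length(pathways),
              dimnames = list(paste(groups$rank, groups$taxon, sep = ":"),
                              names(pathways)))
  for (i in seq_len(nrow(groups))) {
    grp <- list(genome_ids = groups$genome_ids[[i]])
    for (j in seq_along(pathways)) {
      m[i, j] <- pathway_presence(grp, ko_sets, pathways[[j]])$present
    }
  }
  cats <- vapply(pathways, `[[`, character(1), "category")
  cat_summary <- do.call(rbind, lapply(unique(cats), function(cc) {
    cols <- which(cats == cc)
    hit <- apply(m[, cols, drop = FALSE], 1, any)
    data.frame(category = cc,
               n_lineages = sum(hit),
               fraction = sum(hit) / nrow(m),
               stringsAsFactors = FALSE)
  }))
  attr(m, "category_summary") <- cat_summary
  m
}

#' Write a lineage-by-pathway matrix to TSV
#' @param m matrix from [lineage_capability_matrix()].
#' @param path output file.
#' @param provenance optional provenance comment line.
#' @return the path, invisibly.
#' @export
write_lineage_matrix <- function(m, path, provenance = NULL) {
  df <- data.frame(lineage = rownames(m),
                   as.data.frame(m + 0L, check.names = FALSE),
                   check.names = FALSE)
  write_tsv_plain(df, path, provenance)
}
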