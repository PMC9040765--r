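#' @title GTDB-style taxonomy handling and novelty classification
#'
#' @description
#' MAG taxonomy is handled as 7-rank GTDB-style strings
#' (`d__;p__;c__;o__;f__;g__;s__`). Lineages are classified against
#' reference-database genome counts as *novel* (no genomes in the reference),
#' *rare* (5 genomes or less — a lineage of rare distribution, LRD), or
#' *abundant* (more than 5 genomes).
#'
#' @name taxonomy
NULL

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order",
                    "family", "genus", "species")
RANK_PREFIXES <- c("d", "p", "c", "o", "f", "g", "s")

#' Median reference RED value for novel-family designation
#'
#' Relative evolutionary divergence (RED) is a 0-1 branch-depth statistic.
#' The reference median RED at which a lineage is designated a novel family
#' is 0.77; collections averaging near or below it are family-level novel.
#'
#' @export
red_family_median <- 0.77

#' Is a taxon name a novel-lineage placeholder?
#'
#' Placeholder names follow the ZN convention (ZNP/ZNC/ZNO/ZNF/... for novel
#' phylum/class/order/family), optionally suffixed `-<parent or ordinal>`.
#'
#' @param name character vector of taxon names.
#' @return logical vector.
#' @export
is_placeholder_name <- function(name) {
  grepl("^ZN[DPCOFGS](-|$)", name)
}

#' Parse a GTDB-style taxonomy string
#'
#' Accepts 1-7 semicolon-separated rank tokens with standard prefixes
#' (`d__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__`) in rank order starting
#' at domain. Ranks below the last named rank are filled with deterministic
#' ZN-prefixed placeholder names that carry the deepest named parent, e.g.
#' a genome classified only to order `o__X` gets family `ZNF-X`.
#'
#' Trailing empty-name tokens (e.g. `"d__Bacteria;p__"`) are accepted and
#' treated as absent; a named token below an empty one is a gap and is
#' rejected. Strings whose tokens all carry names (ZN placeholders count as
#' names) round-trip losslessly through [serialize_taxonomy()].
#'
#' @param taxonomy_string a single taxonomy string.
#' @return an object of class `ranked_taxonomy`: 7 rank names plus
#'   placeholder flags and the number of ranks given in the input.
#' @export
#' @examples
#' tx <- parse_taxonomy("d__Bacteria;p__Chloroflexota;c__Anaerolineae")
#' tx$ranks[["family"]]   # "ZNF-Anaerolineae", a generated placeholder
parse_taxonomy <- function(taxonomy_string) {
  if (!is.character(taxonomy_string) || length(taxonomy_string) != 1L ||
      is.na(taxonomy_string) || !nzchar(trimws(taxonomy_string))) {
    stop("taxonomy string must be a single non-empty string", call. = FALSE)
  }
  tokens <- trimws(strsplit(taxonomy_string, ";", fixed = TRUE)[[1]])
  if (length(tokens) > 7L) {
    stop("taxonomy string has more than 7 rank tokens: ",
         taxonomy_string, call. = FALSE)
  }
  names_vec <- character(length(tokens))
  for (i in seq_along(tokens)) {
    expected <- paste0(RANK_PREFIXES[i], "__")
    if (!startsWith(tokens[i], expected)) {
      stop("malformed rank token '", tokens[i], "' at position ", i,
           ": expected prefix '", expected, "'", call. = FALSE)
    }
    names_vec[i] <- substring(tokens[i], nchar(expected) + 1L)
  }
  # trailing empty names are "not given"; an empty name above a named one
  # is a gap in the lineage and is invalid
  named <- nzchar(names_vec)
  if (any(named)) {
    last_named <- max(which(named))
    if (!all(named[seq_len(last_named)])) {
      gap <- which(!named[seq_len(last_named)])[1]
      stop("taxonomy gap: rank '", TAXONOMY_RANKS[gap],
           "' is empty but a lower rank is named in ",
           taxonomy_string, call. = FALSE)
    }
  } else {
    stop("taxonomy string names no rank: ", taxonomy_string, call. = FALSE)
  }
  n_given <- last_named
  ranks <- character(7L)
  placeholder <- logical(7L)
  ranks[seq_len(n_given)] <- names_vec[seq_len(n_given)]
  placeholder[seq_len(n_given)] <- is_placeholder_name(ranks[seq_len(n_given)])
  # no named rank may sit below a placeholder rank
  if (n_given > 1L) {
    for (i in 2:n_given) {
      if (!placeholder[i] && any(placeholder[seq_len(i - 1L)])) {
        stop("taxonomy gap: non-placeholder name '", ranks[i],
             "' below a placeholder rank in ", taxonomy_string,
             call. = FALSE)
      }
    }
  }
  if (n_given < 7L) {
    # deepest non-placeholder parent anchors the generated placeholder names
    parent_pool <- ranks[seq_len(n_given)][!placeholder[seq_len(n_given)]]
    parent <- if (length(parent_pool) > 0L) {
      parent_pool[length(parent_pool)]
    } else {
      ranks[n_given]
    }
    for (i in (n_given + 1L):7L) {
      ranks[i] <- paste0("ZN", toupper(RANK_PREFIXES[i]), "-", parent)
      placeholder[i] <- TRUE
    }
  }
  names(ranks) <- TAXONOMY_RANKS
  names(placeholder) <- TAXONOMY_RANKS
  structure(list(ranks = ranks, placeholder = placeholder,
                 n_given = n_given),
            class = "ranked_taxonomy")
}

#' Serialize a parsed taxonomy back to its string form
#'
#' Only the ranks given in the original input are emitted, so
#' `serialize_taxonomy(parse_taxonomy(s))` equals `s` for canonical strings.
#'
#' @param tx a `ranked_taxonomy` object.
#' @param full emit all 7 ranks (generated placeholders included)?
#' @return a single taxonomy string.
#' @export
serialize_taxonomy <- function(tx, full = FALSE) {
  stopifnot(inherits(tx, "ranked_taxonomy"))
  n <- if (full) 7L else tx$n_given
  paste0(RANK_PREFIXES[seq_len(n)], "__", tx$ranks[seq_len(n)],
         collapse = ";")
}

#' @export
print.ranked_taxonomy <- function(x, ...) {
  cat("<ranked_taxonomy> ", serialize_taxonomy(x, full = TRUE), "\n", sep = "")
  invisible(x)
}

#' Build a reference taxon-count table
#'
#' @param df data frame with columns `rank`, `taxon`, `count` (genome count
#'   in the reference database). Absent (rank, taxon) pairs mean count 0.
#' @return object of class `ref_counts`.
#' @export
reference_counts <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("rank", "taxon", "count") %in% names(df)))
  if (!all(df$rank %in% TAXONOMY_RANKS)) {
    bad <- setdiff(unique(df$rank), TAXONOMY_RANKS)
    stop("unknown rank(s) in reference counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- as.integer(df$count)
  if (anyNA(counts) || any(counts < 0L)) {
    stop("reference counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(df$rank, df$taxon, sep = "\t")
  if (anyDuplicated(key)) {
    stop("duplicate (rank, taxon) entries in reference counts", call. = FALSE)
  }
  structure(stats::setNames(counts, key), class = "ref_counts")
}

#' Read a reference taxon-count TSV (columns rank, taxon, count)
#' @param path file path.
#' @return a `ref_counts` object.
#' @export
read_reference_counts <- function(path) {
  reference_counts(read_tsv_strict(path, c("rank", "taxon", "count")))
}

#' Look up reference genome counts (absent taxa count 0)
#'
#' @param ref a `ref_counts` object.
#' @param rank rank name(s).
#' @param taxon taxon name(s).
#' @return integer vector of counts.
#' @export
ref_count <- function(ref, rank, taxon) {
  stopifnot(inherits(ref, "ref_counts"))
  key <- paste(rank, taxon, sep = "\t")
  out <- unclass(ref)[key]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Classify one taxon as novel, rare, or abundant
#'
#' Reference count 0 means novel; 1-5 means rare (lineage of rare
#' distribution, LRD); 6 or more means abundant. Placeholder taxon names
#' (ZN convention) are always novel.
#'
#' @param taxon taxon name.
#' @param rank one of the 7 ranks.
#' @param ref a `ref_counts` object.
#' @return list with `subject`, `rank`, `status`.
#' @export
classify_taxon <- function(taxon, rank, ref) {
  if (!rank %in% TAXONOMY_RANKS) {
    stop("unknown rank: ", rank, call. = FALSE)
  }
  status <- if (is_placeholder_name(taxon)) {
    "novel"
  } else {
    n <- ref_count(ref, rank, taxon)
    if (n == 0L) "novel" else if (n <= 5L) "rare" else "abundant"
  }
  list(subject = taxon, rank = rank, status = status)
}

taxon_status <- function(taxon, rank, ref) {
  # vectorized core of classify_taxon
  n <- ref_count(ref, rank, taxon)
  status <- ifelse(n == 0L, "novel", ifelse(n <= 5L, "rare", "abundant"))
  status[is_placeholder_name(taxon)] <- "novel"
  status
}

#' Read a genome metadata TSV
#'
#' Expected columns: `genome_id`, `habitat` (sediment or water),
#' `taxonomy` (GTDB-style string), `completeness`, `contamination`,
#' `red` (optional values; empty cells allowed). Taxonomy strings are
#' parsed into 7 rank columns. Genomes with contamination above 10% are
#' rejected at load with a message naming them, mirroring the bin-QC
#' admission rule.
#'
#' @param path file path.
#' @return data frame with one row per admitted genome.
#' @export
read_genome_table <- function(path) {
  df <- read_tsv_strict(path, c("genome_id", "habitat", "taxonomy",
                                "completeness", "contamination"))
  if (!"red" %in% names(df)) df$red <- NA_real_
  df$red <- suppressWarnings(as.numeric(df$red))
  genome_collection(df)
}

#' Assemble and validate a genome collection
#'
#' @param df data frame with the columns of [read_genome_table()].
#' @return validated data frame with parsed rank columns
#'   (`domain` .. `species`).
#' @export
genome_collection <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("empty genome table", call. = FALSE)
  if (anyDuplicated(df$genome_id)) {
    stop("duplicate genome_id values: ",
         paste(unique(df$genome_id[duplicated(df$genome_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$habitat %in% c("sediment", "water"))) {
    stop("habitat must be 'sediment' or 'water'", call. = FALSE)
  }
  if (any(df$completeness < 0 | df$completeness > 100) ||
      any(df$contamination < 0 | df$contamination > 100)) {
    stop("completeness/contamination must lie in [0, 100]", call. = FALSE)
  }
  if (any(!is.na(df$red) & (df$red < 0 | df$red > 1))) {
    stop("red values must lie in [0, 1]", call. = FALSE)
  }
  high_cont <- df$contamination > 10
  if (any(high_cont)) {
    message(sum(high_cont), " genome(s) rejected for contamination > 10%: ",
            paste(df$genome_id[high_cont], collapse = ", "))
    df <- df[!high_cont, , drop = FALSE]
    if (nrow(df) == 0L) stop("no genomes pass the contamination bound",
                             call. = FALSE)
  }
  parsed <- lapply(df$taxonomy, parse_taxonomy)
  rank_mat <- do.call(rbind, lapply(parsed, function(tx) tx$ranks))
  for (r in TAXONOMY_RANKS) df[[r]] <- unname(rank_mat[, r])
  rownames(df) <- NULL
  df
}

#' Per-rank novelty profile of one genome
#'
#' @param genome one row of a genome collection (or a list with the 7 rank
#'   fields).
#' @param ref a `ref_counts` object.
#' @param ranks ranks to classify (default phylum..family plus genus and
#'   species when named).
#' @return named character vector of statuses.
#' @export
genome_novelty_profile <- function(genome, ref,
                                   ranks = TAXONOMY_RANKS[2:5]) {
  stats::setNames(
    vapply(ranks, function(r) taxon_status(genome[[r]], r, ref),
           character(1)),
    ranks)
}

#' Novelty summary of a genome collection at one rank
#'
#' Counts genomes and distinct taxa per status and reports percentages
#' (half-up rounding, two decimals). The combined novel-plus-rare genome
#' percentage at family rank is the headline novelty statistic.
#'
#' @param genomes a genome collection data frame.
#' @param ref a `ref_counts` object.
#' @param rank rank to summarize at (default `"family"`).
#' @return list with genome counts, taxon counts and percentages.
#' @export
novelty_summary <- function(genomes, ref, rank = "family") {
  stopifnot(rank %in% TAXONOMY_RANKS)
  if (!is.data.frame(genomes) || nrow(genomes) == 0L) {
    stop("empty genome collection", call. = FALSE)
  }
  taxa <- genomes[[rank]]
  status <- taxon_status(taxa, rank, ref)
  n <- nrow(genomes)
  n_novel <- sum(status == "novel")
  n_rare <- sum(status == "rare")
  per_taxon <- tapply(status, taxa, function(s) s[1])
  list(
    rank = rank,
    n_genomes = n,
    n_genomes_novel = n_novel,
    n_genomes_rare = n_rare,
    pct_novel = round_half_up(100 * n_novel / n, 2),
    pct_rare = round_half_up(100 * n_rare / n, 2),
    pct_combined = round_half_up(100 * (n_novel + n_rare) / n, 2),
    n_taxa_novel = sum(per_taxon == "novel"),
    n_taxa_rare = sum(per_taxon == "rare"),
    n_taxa_abundant = sum(per_taxon == "abundant")
  )
}

#' Database enrichment of an order by this study
#'
#' The number of genomes binned in the study for an order as a percentage
#' of the number of genomes of that order in the reference database.
#' Orders absent from the reference (novel orders) have no defined
#' enrichment and return `NA` with a `"reason"` attribute.
#'
#' @param taxon order name.
#' @param study_count number of study genomes in the order.
#' @param ref a `ref_counts` object.
#' @return percentage, or `NA` for a novel order.
#' @export
database_enrichment <- function(taxon, study_count, ref) {
  if (!is.numeric(study_count) || length(study_count) != 1L ||
      is.na(study_count) || study_count < 0) {
    stop("study_count must be a single non-negative number", call. = FALSE)
  }
  denom <- ref_count(ref, "order", taxon)
  if (denom == 0L) {
    return(structure(NA_real_, reason = "undefined (novel order)"))
  }
  100 * study_count / denom
}

#' Mean relative evolutionary divergence (RED) of a collection
#'
#' Arithmetic mean of the supplied RED values, rounded half-up to two
#' decimals; genomes lacking a RED value are excluded and counted in the
#' `n_missing` attribute.
#'
#' @param genomes a genome collection data frame (column `red`).
#' @return mean RED with attributes `n_used` and `n_missing`.
#' @export
mean_red <- function(genomes) {
  red <- genomes$red
  ok <- !is.na(red)
  if (!any(ok)) stop("no RED values present in the collection", call. = FALSE)
  structure(round_half_up(mean(red[ok]), 2),
            n_used = sum(ok), n_missing = sum(!ok))
}

#' Partition water genomes into sediment-shared and water-specific families
#'
#' A water genome is *shared* iff its family name occurs among the family
#' names of the sediment genomes; otherwise it is *water-specific*.
#'
#' @param sediment,water genome collection data frames (column `family`).
#' @return list with `n_water_shared`, `n_water_specific` and the family
#'   name lists.
#' @export
shared_family_partition <- function(sediment, water) {
  sed_fams <- unique(sediment$family)
  shared <- water$family %in% sed_fams
  list(
    n_water_shared = sum(shared),
    n_water_specific = sum(!shared),
    shared_families = sort(unique(water$family[shared])),
    specific_families = sort(unique(water$family[!shared]))
  )
}
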