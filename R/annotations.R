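#' @title Gene-hit and KO-annotation loading
#'
#' @description
#' Profile-HMM scan output (genome, gene symbol, alignment bit score) is
#' reduced to per-genome presence sets over a controlled sulfur-gene
#' vocabulary, keeping only hits at or above a bit-score threshold
#' (default 100, the `-T 100` convention of hmmscan). KO annotations
#' (GhostKOALA-style, `K#####`) become per-genome KO sets.
#'
#' @name annotations
NULL

#' Controlled vocabulary of dissimilatory sulfur-cycling gene symbols
#'
#' Canonical subunit symbols of the sulfate-reduction (Sat, AprAB, QmoABC),
#' sulfite-reduction (DsrABC plus the DsrKMJOP membrane module, the DsrD and
#' DsrEFH accessories, AsrABC, HdrABC), polysulfide/thiosulfate/tetrathionate
#' reduction (PsrABC, PhsABC, TtrABC, Otr), sulfurhydrogenase (HydABCD,
#' ShyABCD), rhodanese-like thiosulfate disproportionation (Rhd, covering
#' EC 2.8.1.1 and EC 2.8.1.3), and oxidation systems (SoxAXBYZCD, FccAB,
#' Sqr, SoeABC, SorAB, TsdA, DoxAD, TetH).
#'
#' @return character vector of canonical gene symbols.
#' @export
sulfur_gene_vocabulary <- function() {
  c("Sat", "AprA", "AprB", "QmoA", "QmoB", "QmoC",
    "DsrA", "DsrB", "DsrC", "DsrK", "DsrM", "DsrJ", "DsrO", "DsrP",
    "DsrD", "DsrE", "DsrF", "DsrH",
    "AsrA", "AsrB", "AsrC", "HdrA", "HdrB", "HdrC",
    "PsrA", "PsrB", "PsrC", "PhsA", "PhsB", "PhsC",
    "TtrA", "TtrB", "TtrC", "Otr",
    "HydA", "HydB", "HydC", "HydD", "ShyA", "ShyB", "ShyC", "ShyD",
    "Rhd",
    "SoxA", "SoxB", "SoxC", "SoxD", "SoxX", "SoxY", "SoxZ",
    "FccA", "FccB", "Sqr", "SoeA", "SoeB", "SoeC", "SorA", "SorB",
    "TsdA", "DoxA", "DoxD", "TetH")
}

# extra spellings beyond case variants of the canonical symbols
GENE_ALIASES <- c(
  "rhodanese" = "Rhd",
  "rhodanase" = "Rhd",
  "ec2.8.1.1" = "Rhd",
  "ec2.8.1.3" = "Rhd",
  "teth"      = "TetH",
  "otr"       = "Otr",
  "sqr"       = "Sqr",
  "tsda"      = "TsdA"
)

#' Normalize gene symbols to the canonical vocabulary
#'
#' Resolution is case-insensitive over the canonical symbols plus an alias
#' map (rhodanese spellings and EC numbers map to `Rhd`). Unresolvable
#' symbols come back as `NA`, never silently kept.
#'
#' @param symbols character vector of raw gene symbols.
#' @return character vector of canonical symbols, `NA` where unknown.
#' @export
normalize_gene_symbol <- function(symbols) {
  vocab <- sulfur_gene_vocabulary()
  lut <- stats::setNames(vocab, tolower(vocab))
  lut <- c(lut, GENE_ALIASES)
  out <- lut[tolower(trimws(symbols))]
  unname(out)
}

#' Load a gene-hit table into per-genome presence sets
#'
#' Reads a TSV with header `genome_id`, `gene_symbol`, `bit_score` and an
#' optional logical `confirmed` column (rows marked false — hits that failed
#' downstream phylogenetic vetting — are dropped). Hits with
#' `bit_score >= threshold` contribute to the presence sets; the comparison
#' is inclusive, so a score of exactly 100 is retained at the default
#' threshold. Unknown gene symbols are collected into a rejects report
#' (attribute `rejects`, with a warning), and the number of sub-threshold
#' hits is recorded in attribute `n_discarded`.
#'
#' @param path hit-table file.
#' @param threshold minimum alignment bit score (default 100).
#' @return named list `genome_id -> sorted character vector of gene
#'   symbols` of class `gene_presence`.
#' @export
load_hits <- function(path, threshold = 100) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  df <- read_tsv_strict(path, c("genome_id", "gene_symbol", "bit_score"))
  gene_presence(df, threshold = threshold)
}

#' Build presence sets from an in-memory hit table
#'
#' @param hits data frame with columns `genome_id`, `gene_symbol`,
#'   `bit_score` and optionally `confirmed`.
#' @param threshold minimum alignment bit score.
#' @return a `gene_presence` object (see [load_hits()]).
#' @export
gene_presence <- function(hits, threshold = 100) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    return(structure(list(), n_discarded = 0L,
                     rejects = character(0), class = "gene_presence"))
  }
  score <- suppressWarnings(as.numeric(hits$bit_score))
  bad <- which(is.na(score) | score < 0)
  if (length(bad) > 0L) {
    stop("malformed bit_score at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if ("confirmed" %in% names(hits)) {
    keep_conf <- !(hits$confirmed %in% c(FALSE, "FALSE", "false", "0"))
    hits <- hits[keep_conf, , drop = FALSE]
    score <- score[keep_conf]
  }
  canon <- normalize_gene_symbol(hits$gene_symbol)
  rejects <- sort(unique(hits$gene_symbol[is.na(canon)]))
  if (length(rejects) > 0L) {
    warning("unknown gene symbol(s) rejected: ",
            paste(rejects, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(canon) & score >= threshold
  n_discarded <- sum(!is.na(canon) & score < threshold)
  sets <- lapply(split(canon[keep], hits$genome_id[keep]),
                 function(g) sort(unique(g)))
  structure(sets, n_discarded = n_discarded, rejects = rejects,
            class = "gene_presence")
}

#' Genes present in one genome
#' @param presence a `gene_presence` object.
#' @param genome_id genome identifier.
#' @return character vector (empty if the genome has no retained hits).
#' @export
genes_of <- function(presence, genome_id) {
  presence[[genome_id]] %||% character(0)
}

#' Load a KO annotation table into per-genome KO sets
#'
#' Reads a TSV with header `genome_id`, `ko`. KO identifiers must match the
#' `K#####` pattern; a non-conforming identifier aborts with its line
#' number. Duplicate (genome, KO) rows collapse to set membership.
#'
#' @param path KO-table file.
#' @return named list `genome_id -> sorted character vector of KO ids`.
#' @export
load_ko_table <- function(path) {
  df <- read_tsv_strict(path, c("genome_id", "ko"))
  if (nrow(df) == 0L) return(list())
  ok <- grepl("^K[0-9]{5}$", df$ko)
  if (!all(ok)) {
    first_bad <- which(!ok)[1]
    stop("non-conforming KO id '", df$ko[first_bad], "' at line ",
         first_bad + 1L, " of ", path, call. = FALSE)
  }
  lapply(split(df$ko, df$genome_id), function(k) sort(unique(k)))
}
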