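# Shared helpers: small genome-table builders, a cached headline fixture,
# and an independent brute-force capability evaluator used as the oracle
# for the rule engine.

.fixture_cache <- new.env(parent = emptyenv())

get_headline_fixture <- function() {
  if (is.null(.fixture_cache$headline)) {
    .fixture_cache$headline <- generate_fixture(headline_fixture())
  }
  .fixture_cache$headline
}

get_headline_calls <- function() {
  if (is.null(.fixture_cache$calls)) {
    fx <- get_headline_fixture()
    .fixture_cache$calls <- call_genomes(gene_presence(fx$hits), fx$genomes)
  }
  .fixture_cache$calls
}

# minimal genome table: one genome per row from taxonomy strings
make_genomes <- function(taxonomies, habitat = "sediment",
                         ids = sprintf("g%03d", seq_along(taxonomies)),
                         red = NA_real_) {
  genome_collection(data.frame(
    genome_id = ids, habitat = habitat, taxonomy = taxonomies,
    completeness = 90, contamination = 1, red = red,
    stringsAsFactors = FALSE))
}

make_ref <- function(rank = character(0), taxon = character(0),
                     count = integer(0)) {
  reference_counts(data.frame(rank = rank, taxon = taxon, count = count,
                              stringsAsFactors = FALSE))
}

# ---- independent brute-force capability oracle -----------------------------
# Naive per-rule set-inclusion checks, written directly from the capability
# definitions with no shared code with the expression engine.

bf_evaluate <- function(genes, taxa = character(0)) {
  has <- function(...) all(c(...) %in% genes)
  any_of <- function(...) any(c(...) %in% genes)
  sat <- list()
  sat$sulfate_reduction <- has("Sat", "AprA", "AprB", "QmoA", "QmoB",
                               "QmoC", "DsrA", "DsrB", "DsrC")
  dsr_excluded <- any(c("Proteobacteria", "Nitrospirota", "Nitrospira",
                        "Chlorobiaceae") %in% taxa)
  sat$sulfite_reduction_dsr <- has("DsrA", "DsrB", "DsrC") &&
    sum(c("DsrK", "DsrM", "DsrJ", "DsrO", "DsrP") %in% genes) >= 3 &&
    !dsr_excluded
  sat$sulfite_reduction_asr <- has("AsrA", "AsrB", "AsrC")
  sat$polysulfide_reduction <- has("PsrA", "PsrB", "PsrC")
  sat$sulfurhydrogenase <- has("HydA", "HydB", "HydC", "HydD") ||
    has("ShyA", "ShyB", "ShyC", "ShyD")
  sat$thiosulfate_reduction <- has("PhsA", "PhsB", "PhsC") &&
    (has("DsrA", "DsrB", "DsrC") || has("AsrA", "AsrB", "AsrC"))
  sat$thiosulfate_disproportionation_phs <- has("PhsA", "PhsB", "PhsC") &&
    (has("AprA", "AprB", "Sat") || has("SoeA", "SoeB", "SoeC") ||
       any_of("SorA"))
  sat$thiosulfate_disproportionation_rhd <- any_of("Rhd") &&
    (has("Sat", "AprA", "AprB") || has("SoeA", "SoeB", "SoeC")) &&
    (has("DsrA", "DsrB", "DsrC") || has("AsrA", "AsrB", "AsrC"))
  sat$tetrathionate_reduction <- any_of("Otr") ||
    has("TtrA", "TtrB", "TtrC")
  sat$sox_complete <- has("SoxA", "SoxX", "SoxB", "SoxY", "SoxZ",
                          "SoxC", "SoxD")
  sat$sulfide_oxidation <- has("FccA", "FccB") || any_of("Sqr")
  sat$sulfur_oxidation_rdsr <- has("DsrA", "DsrB", "DsrC") &&
    (has("FccA", "FccB") || any_of("Sqr")) &&
    !has("Sat", "AprA", "AprB", "QmoA", "QmoB", "QmoC")
  other_ox <- sat$sox_complete || sat$sulfide_oxidation ||
    sat$sulfur_oxidation_rdsr ||
    any_of("TsdA") || has("DoxA", "DoxD") || any_of("TetH")
  sat$sulfite_oxidation <-
    (has("AprA", "AprB", "QmoA", "QmoB", "QmoC", "Sat") && other_ox) ||
    has("SoeA", "SoeB", "SoeC") || has("SorA", "SorB")
  sat$thiosulfate_oxidation_tetrathionate <- any_of("TsdA") ||
    has("DoxA", "DoxD")
  sat$tetrathionate_hydrolysis <- any_of("TetH")

  active <- sat
  # suppression: a full sulfate reducer is not also a sulfite-only reducer
  if (isTRUE(sat$sulfate_reduction)) active$sulfite_reduction_dsr <- FALSE
  list(satisfied = sat, active = active)
}

bf_directions <- c(
  sulfate_reduction = "reduction",
  sulfite_reduction_dsr = "reduction",
  sulfite_reduction_asr = "reduction",
  polysulfide_reduction = "reduction",
  sulfurhydrogenase = "flag",
  thiosulfate_reduction = "reduction",
  thiosulfate_disproportionation_phs = "disproportionation",
  thiosulfate_disproportionation_rhd = "disproportionation",
  tetrathionate_reduction = "reduction",
  sox_complete = "oxidation",
  sulfide_oxidation = "oxidation",
  sulfur_oxidation_rdsr = "oxidation",
  sulfite_oxidation = "oxidation",
  thiosulfate_oxidation_tetrathionate = "oxidation",
  tetrathionate_hydrolysis = "oxidation"
)

# active capability names from the engine for one genome
engine_active <- function(genes, taxonomy = NULL,
                          ruleset = default_ruleset()) {
  calls <- call_genome("g", genes, taxonomy, ruleset)
  sort(calls$capability[calls$active])
}

random_gene_set <- function() {
  vocab <- sulfur_gene_vocabulary()
  n <- sample(0:25, 1)
  sample(vocab, n)
}

write_hits_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
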