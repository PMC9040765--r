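#!/usr/bin/env Rscript
# Stage 2 — novelty/rarity classification against reference genome counts.
#
# Classifies every genome's family as novel (0 reference genomes), rare
# (1-5) or abundant (>5), summarizes per habitat, computes mean RED and
# the water/sediment family-sharing partition.

library(sulfurMAGs)

fixture <- file.path("scratch", "fixture")
genomes <- read_genome_table(file.path(fixture, "genome_metadata.tsv"))
ref <- read_reference_counts(file.path(fixture, "reference_counts.tsv"))

sed <- genomes[genomes$habitat == "sediment", ]
wat <- genomes[genomes$habitat == "water", ]

s <- novelty_summary(sed, ref, "family")
cat(sprintf(
  "Sediment: %d/%d genomes (%.2f%%) in novel or rare families\n",
  s$n_genomes_novel + s$n_genomes_rare, s$n_genomes, s$pct_combined))
cat(sprintf("  %d novel families (%d genomes, %.2f%%)\n",
            s$n_taxa_novel, s$n_genomes_novel, s$pct_novel))
cat(sprintf("  %d rare families (%d genomes, %.2f%%)\n",
            s$n_taxa_rare, s$n_genomes_rare, s$pct_rare))

m <- mean_red(sed)
cat(sprintf(
  "  mean RED %.2f over %d genomes (novel-family median reference: %.2f)\n",
  m, attr(m, "n_used"), red_family_median))

sw <- novelty_summary(wat, ref, "family")
cat(sprintf("Water: %.2f%% of %d genomes in novel or rare families\n",
            sw$pct_combined, sw$n_genomes))
part <- shared_family_partition(sed, wat)
cat(sprintf("  %d water genomes in sediment-shared families, %d specific\n",
            part$n_water_shared, part$n_water_specific))

out <- do.call(rbind, lapply(list(list(sed, "sediment"), list(wat, "water")),
  function(x) {
    ss <- novelty_summary(x[[1]], ref, "family")
    data.frame(habitat = x[[2]], ss[setdiff(names(ss), "rank")])
  }))
write.table(out, file.path("results", "novelty_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/novelty_summary.tsv\n")
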