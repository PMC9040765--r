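#!/usr/bin/env Rscript
# Stage 5 — transcript-abundance aggregation.
#
# Sums TPM per sulfur gene group and phylum for each of the three diel
# samples plus a pooled view, and reports the Asr:Dsr expression ratio.

library(sulfurMAGs)

fixture <- file.path("scratch", "fixture")
genomes <- read_genome_table(file.path(fixture, "genome_metadata.tsv"))
tpm <- read_tpm_table(file.path(fixture, "transcript_abundance.tsv"))

agg <- aggregate_tpm(tpm, default_gene_groups(), genomes)

cat("Pooled TPM per gene group:\n")
pg <- agg$pooled_group_totals
for (i in order(-pg$tpm_sum)) {
  cat(sprintf("  %-32s %8.1f\n", pg$group[i], pg$tpm_sum[i]))
}
r <- expression_ratio(agg, "asr_system", "dsr_system")
cat(sprintf("Asr:Dsr expression ratio (pooled): %.2f\n", r))
for (s in unique(tpm$sample_id)) {
  cat(sprintf("  %s: %.2f\n", s,
              expression_ratio(agg, "asr_system", "dsr_system", s)))
}

write.table(agg$by_phylum, file.path("results", "tpm_group_phylum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(agg$group_totals, file.path("results", "tpm_group_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/tpm_group_phylum.tsv, tpm_group_totals.tsv\n")
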