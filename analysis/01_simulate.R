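#!/usr/bin/env Rscript
# Stage 1 — generate the headline community fixture.
#
# Writes the five input tables (genome metadata, reference taxon counts,
# gene hits, KO annotations, transcript abundances) plus the ground-truth
# manifest under scratch/fixture/ (regenerable working data; the findings
# tables of later stages go under results/). Everything downstream reads
# from there.

library(sulfurMAGs)

out <- file.path("scratch", "fixture")
fx <- generate_fixture(headline_fixture(), out_dir = out)

cat("Fixture written to", out, "\n")
cat(sprintf("  %d sediment + %d water genomes\n",
            fx$manifest$n_sediment, fx$manifest$n_water))
cat(sprintf("  planted: %d novel-family genomes over %d novel families,\n",
            fx$manifest$counts$novel_genomes,
            fx$manifest$counts$novel_families))
cat(sprintf("           %d rare-family genomes over %d rare families\n",
            fx$manifest$counts$rare_genomes,
            fx$manifest$counts$rare_families))
cat(sprintf("  %d gene-hit rows, %d KO rows, %d TPM rows\n",
            nrow(fx$hits), nrow(fx$ko), nrow(fx$tpm)))
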