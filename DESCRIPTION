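Package: sulfurMAGs
Title: Novelty Classification and Sulfur-Cycling Capability Calling for
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision layer over metagenome-assembled-genome (MAG)
    collections from stratified sulfidic habitats: classifies lineages as
    novel, rare, or abundant against reference-database genome counts
    (GTDB-style taxonomy strings), calls reductive, disproportionating and
    oxidative dissimilatory sulfur-cycling capabilities from profile-HMM
    gene hits via a declarative boolean rule set, infers lineage-level
    metabolic pathway presence with an 80-percent-of-KOs rule, and
    aggregates metatranscriptome TPM values per gene group and phylum.
    Ships a seeded synthetic fixture generator so every stage is testable
    without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
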