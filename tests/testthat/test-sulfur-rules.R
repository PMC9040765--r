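sulfate_set <- c("Sat", "AprA", "AprB", "QmoA", "QmoB", "QmoC",
                 "DsrA", "DsrB", "DsrC")

test_that("the shipped rule set loads and references only known symbols", {
  rs <- default_ruleset()
  expect_length(rs, 15)
  expect_true(all(vapply(rs, function(r) r$direction, character(1)) %in%
                    c("reduction", "disproportionation", "oxidation",
                      "flag")))
})

test_that("capability examples evaluate as defined", {
  rs <- default_ruleset()
  # the full sulfate gene complement calls sulfate reduction
  expect_true("sulfate_reduction" %in% engine_active(sulfate_set))
  # AsrABC alone calls Asr sulfite reduction without the Hdr annotation
  calls <- call_genome("g", c("AsrA", "AsrB", "AsrC"))
  asr <- calls[calls$capability == "sulfite_reduction_asr", ]
  expect_true(asr$active)
  expect_equal(asr$annotations, "")
  # with the adjacent Hdr locus the annotation appears
  calls2 <- call_genome("g", c("AsrA", "AsrB", "AsrC",
                               "HdrA", "HdrB", "HdrC"))
  expect_equal(
    calls2$annotations[calls2$capability == "sulfite_reduction_asr"],
    "asr_hdr_locus")
  # no genes, no calls
  expect_equal(nrow(call_genome("g", character(0))), 0L)
  # PhsABC + SoeABC disproportionates thiosulfate
  expect_true("thiosulfate_disproportionation_phs" %in%
                engine_active(c("PhsA", "PhsB", "PhsC",
                                "SoeA", "SoeB", "SoeC")))
})

test_that("a full sulfate reducer has its Dsr-only call suppressed, not deleted", {
  genes <- c(sulfate_set, "DsrK", "DsrM", "DsrJ")
  calls <- call_genome("g", genes)
  dsr <- calls[calls$capability == "sulfite_reduction_dsr", ]
  expect_equal(nrow(dsr), 1L)
  expect_false(dsr$active)
  expect_equal(dsr$suppressed_by, "sulfate_reduction")
  expect_true(calls$active[calls$capability == "sulfate_reduction"])
  # without the sulfate genes the same membrane complex is an active call
  calls2 <- call_genome("g", c("DsrA", "DsrB", "DsrC",
                               "DsrK", "DsrM", "DsrJ"))
  expect_true(calls2$active[calls2$capability == "sulfite_reduction_dsr"])
})

test_that("taxon exclusions veto the reductive Dsr call for oxidative lineages", {
  genes <- c("DsrA", "DsrB", "DsrC", "DsrK", "DsrM", "DsrJ")
  tx <- parse_taxonomy("d__Bacteria;p__Proteobacteria;c__G;o__O;f__F")
  calls <- call_genome("g", genes, tx)
  expect_false("sulfite_reduction_dsr" %in% calls$capability)
  # same genes in an unexcluded phylum: active
  tx2 <- parse_taxonomy("d__Bacteria;p__Chloroflexota;c__A;o__O;f__F")
  calls2 <- call_genome("g", genes, tx2)
  expect_true(calls2$active[calls2$capability == "sulfite_reduction_dsr"])
})

test_that("evidence is the minimal left-to-right satisfying subset", {
  # Otr branch satisfies tetrathionate reduction; the partial Ttr set
  # contributes nothing
  calls <- call_genome("g", c("Otr", "TtrA"))
  tet <- calls[calls$capability == "tetrathionate_reduction", ]
  expect_equal(tet$evidence, "Otr")
  # evidence soundness: the evidence subset alone reproduces every call
  set.seed(21)
  for (rep in 1:30) {
    genes <- random_gene_set()
    calls <- call_genome("g", genes)
    for (i in seq_len(nrow(calls))) {
      if (!calls$active[i]) next
      ev <- strsplit(calls$evidence[i], ",", fixed = TRUE)[[1]]
      re_calls <- call_genome("g", ev)
      expect_true(calls$capability[i] %in%
                    re_calls$capability[re_calls$active],
                  info = paste(calls$capability[i], "on",
                               paste(genes, collapse = "+")))
    }
  }
})

test_that("the reversal route of sulfite oxidation needs oxidative context", {
  apr_set <- c("AprA", "AprB", "QmoA", "QmoB", "QmoC", "Sat")
  # sulfate genes alone (plus DsrABC they'd be a sulfate reducer): the
  # reversal branch must not fire in a non-oxidative genome
  expect_false("sulfite_oxidation" %in% engine_active(apr_set))
  # the same genes in a genome that also oxidizes sulfide do fire
  expect_true("sulfite_oxidation" %in% engine_active(c(apr_set, "Sqr")))
  # SoeABC needs no context
  expect_true("sulfite_oxidation" %in%
                engine_active(c("SoeA", "SoeB", "SoeC")))
})

test_that("engine calls equal the brute-force oracle on random genomes", {
  rs <- default_ruleset()
  taxa_pool <- list(character(0), "Proteobacteria",
                    c("Bacteria", "Nitrospirota"), "Chlorobiaceae",
                    c("Bacteria", "Chloroflexota"))
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(1:50, 1)
    for (i in seq_len(n)) {
      genes <- random_gene_set()
      taxa <- taxa_pool[[sample(length(taxa_pool), 1)]]
      bf <- bf_evaluate(genes, taxa)
      bf_active <- sort(names(Filter(isTRUE, bf$active)))
      # the oracle has no taxon veto for non-Dsr rules; apply the same veto
      if (any(c("Proteobacteria", "Nitrospirota", "Nitrospira",
                "Chlorobiaceae") %in% taxa)) {
        bf_active <- setdiff(bf_active, "sulfite_reduction_dsr")
      }
      expect_identical(engine_active(genes, taxa, rs), bf_active,
                       info = paste("seed", seed, "genes",
                                    paste(genes, collapse = "+")))
    }
  }
})

test_that("adding genes never removes active calls of exclusion-free rules", {
  excl_rules <- c("sulfite_reduction_dsr", "sulfur_oxidation_rdsr")
  set.seed(33)
  vocab <- sulfur_gene_vocabulary()
  for (rep in 1:40) {
    genes <- random_gene_set()
    extra <- sample(setdiff(vocab, genes),
                    min(5, length(setdiff(vocab, genes))))
    before <- setdiff(engine_active(genes), excl_rules)
    after <- engine_active(c(genes, extra))
    expect_true(all(before %in% after),
                info = paste("lost:", paste(setdiff(before, after),
                                            collapse = ",")))
  }
})

test_that("documented exceptions to monotonicity behave as designed", {
  # gaining the full sulfate complement demotes the Dsr-only call
  dsr_genes <- c("DsrA", "DsrB", "DsrC", "DsrK", "DsrM", "DsrJ")
  expect_true("sulfite_reduction_dsr" %in% engine_active(dsr_genes))
  expect_false("sulfite_reduction_dsr" %in%
                 engine_active(c(dsr_genes, "Sat", "AprA", "AprB",
                                 "QmoA", "QmoB", "QmoC")))
  # gaining the sulfate complement also withdraws the reverse-Dsr call
  rdsr_genes <- c("DsrA", "DsrB", "DsrC", "Sqr")
  expect_true("sulfur_oxidation_rdsr" %in% engine_active(rdsr_genes))
  expect_false("sulfur_oxidation_rdsr" %in%
                 engine_active(c(rdsr_genes, "Sat", "AprA", "AprB",
                                 "QmoA", "QmoB", "QmoC")))
})

test_that("call summaries match a brute-force scan on small collections", {
  set.seed(55)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    hab <- sample(c("sediment", "water"), n, replace = TRUE)
    g <- make_genomes(paste0("d__B;p__P", sample(1:4, n, replace = TRUE),
                             ";c__C;o__O;f__F", sample(1:6, n,
                                                       replace = TRUE)),
                      habitat = hab)
    gene_sets <- replicate(n, random_gene_set(), simplify = FALSE)
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (length(gene_sets[[i]]) == 0) return(NULL)
      data.frame(genome_id = g$genome_id[i], gene_symbol = gene_sets[[i]],
                 bit_score = 200)
    }))
    if (is.null(hits)) next
    presence <- gene_presence(hits)
    calls <- call_genomes(presence, g)
    summ <- summarize_calls(calls, g)
    # brute force over (genome x rule)
    for (h in unique(hab)) {
      red <- ox <- 0L
      for (i in which(hab == h)) {
        bf <- bf_evaluate(gene_sets[[i]], character(0))
        act <- names(Filter(isTRUE, bf$active))
        if (any(bf_directions[act] %in%
                c("reduction", "disproportionation"))) red <- red + 1L
        if (any(bf_directions[act] == "oxidation")) ox <- ox + 1L
      }
      row <- summ$habitat_totals[summ$habitat_totals$habitat == h, ]
      expect_equal(row$reductive_any, red)
      expect_equal(row$oxidative_any, ox)
    }
  }
})

test_that("capability overlap satisfies inclusion-exclusion", {
  g <- make_genomes(rep("d__B;p__P;c__C;o__O;f__F", 6),
                    ids = paste0("g", 1:6))
  # g1,g2 Otr only; g3,g4,g5 Psr only; g6 both
  hits <- rbind(
    data.frame(genome_id = c("g1", "g2", "g6"), gene_symbol = "Otr",
               bit_score = 200),
    do.call(rbind, lapply(c("g3", "g4", "g5", "g6"), function(id)
      data.frame(genome_id = id, gene_symbol = c("PsrA", "PsrB", "PsrC"),
                 bit_score = 200))))
  calls <- call_genomes(gene_presence(hits), g)
  ov <- capability_overlap(calls, "tetrathionate_reduction",
                           "polysulfide_reduction")
  expect_equal(ov, list(n_a = 3L, n_b = 4L, n_both = 1L, n_union = 6L))
  expect_equal(ov$n_union, ov$n_a + ov$n_b - ov$n_both)
  expect_error(capability_overlap(calls, "tetrathionate_reduction",
                                  "warp_drive"), "unknown capability")
  # property on random fixtures
  set.seed(77)
  for (rep in 1:10) {
    calls <- get_headline_calls()
    caps <- sample(attr(calls, "capabilities"), 2)
    ov <- capability_overlap(calls, caps[1], caps[2])
    expect_equal(ov$n_union, ov$n_a + ov$n_b - ov$n_both)
  }
})

test_that("rule files are validated at load, not evaluation", {
  bad1 <- tempfile(fileext = ".yaml")
  writeLines(c("rules:", "- name: r1", "  direction: reduction",
               "  require:", "    all: [NotAGene]"), bad1)
  expect_error(load_ruleset(bad1), "NotAGene")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "- name: r1", "  direction: reduction",
               "  require: {all: [DsrA]}",
               "  exclude_capabilities: [r2]",
               "- name: r2", "  direction: reduction",
               "  require: {all: [DsrB]}",
               "  exclude_capabilities: [r1]"), bad2)
  expect_error(load_ruleset(bad2), "cyclic")
  bad3 <- tempfile(fileext = ".yaml")
  writeLines(c("rules:", "- name: r1", "  direction: sideways",
               "  require: {all: [DsrA]}"), bad3)
  expect_error(load_ruleset(bad3), "direction")
})
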