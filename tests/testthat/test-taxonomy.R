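test_that("taxonomy strings parse, fill placeholders, and round-trip", {
  tx <- parse_taxonomy(
    "d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__ZNF-1")
  expect_equal(unname(tx$ranks[["family"]]), "ZNF-1")
  expect_true(tx$placeholder[["family"]])
  expect_false(tx$placeholder[["order"]])
  # generated ranks below the last named rank carry the deepest named parent
  expect_equal(unname(tx$ranks[["genus"]]), "ZNG-Anaerolineales")
  expect_true(all(tx$placeholder[c("genus", "species")]))

  tx2 <- parse_taxonomy("d__Archaea")
  expect_true(all(tx2$placeholder[2:7]))
  expect_equal(unname(tx2$ranks[["phylum"]]), "ZNP-Archaea")

  canonical <- c(
    "d__Archaea",
    "d__Bacteria;p__Desulfobacterota",
    "d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__ZNF-1",
    "d__Bacteria;p__A;c__B;o__C;f__D;g__E;s__E sp1")
  for (s in canonical) {
    expect_identical(serialize_taxonomy(parse_taxonomy(s)), s)
  }
})

test_that("malformed taxonomy strings are rejected with the offending token", {
  expect_error(parse_taxonomy("p__Bacteria;d__X"), "p__Bacteria")
  expect_error(parse_taxonomy(""), "non-empty")
  expect_error(parse_taxonomy("d__Bacteria;x__Y"), "x__Y")
  # gap: empty rank above a named one
  expect_error(parse_taxonomy("d__Bacteria;p__;c__Anaerolineae"), "gap")
  # gap: real name below an explicit placeholder
  expect_error(parse_taxonomy("d__Bacteria;p__ZNP-1;c__Anaerolineae"), "gap")
})

test_that("taxon classification follows the 0 / 1-5 / 6+ reference bands", {
  ref <- make_ref(rep("family", 2), c("FamRare", "FamBig"), c(5L, 6L))
  expect_equal(classify_taxon("FamAbsent", "family", ref)$status, "novel")
  expect_equal(classify_taxon("FamRare", "family", ref)$status, "rare")
  expect_equal(classify_taxon("FamBig", "family", ref)$status, "abundant")
  # placeholder names are novel regardless of any reference entry
  expect_equal(classify_taxon("ZNF-1", "family", ref)$status, "novel")
  expect_error(classify_taxon("x", "tribe", ref), "rank")
})

test_that("status is exhaustive and monotone in the reference count", {
  for (count in 0:12) {
    ref <- make_ref("family", "F", count)
    st <- classify_taxon("F", "family", ref)$status
    expect_true(st %in% c("novel", "rare", "abundant"))
  }
  rank_of <- c(novel = 1L, rare = 2L, abundant = 3L)
  sts <- vapply(0:12, function(count) {
    classify_taxon("F", "family", make_ref("family", "F", count))$status
  }, character(1))
  expect_true(all(diff(rank_of[sts]) >= 0))
})

test_that("per-rank novelty profiles treat ranks independently", {
  ref <- make_ref(c("family", "order"), c("FamX", "OrdY"), c(3L, 40L))
  g <- make_genomes("d__Bacteria;p__P;c__C;o__OrdY;f__FamX")
  prof <- genome_novelty_profile(g[1, ], ref)
  expect_equal(unname(prof[["family"]]), "rare")
  expect_equal(unname(prof[["order"]]), "abundant")
  expect_equal(unname(prof[["phylum"]]), "novel")  # absent from reference
})

test_that("novelty summaries agree with a brute-force tally", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    fams <- sprintf("F%02d", sample(1:12, n, replace = TRUE))
    counts <- sample(0:10, 12, replace = TRUE)
    ref <- make_ref(rep("family", 12), sprintf("F%02d", 1:12), counts)
    g <- make_genomes(paste0("d__B;p__P;c__C;o__O;f__", fams))
    s <- novelty_summary(g, ref, "family")
    cnt <- counts[as.integer(substring(fams, 2))]
    expect_identical(s$n_genomes_novel, sum(cnt == 0))
    expect_identical(s$n_genomes_rare, sum(cnt >= 1 & cnt <= 5))
    expect_equal(s$pct_combined,
                 floor(100 * 100 * sum(cnt <= 5) / n + 0.5) / 100)
    expect_identical(s$n_taxa_novel,
                     length(unique(fams[cnt == 0])))
    expect_identical(s$n_taxa_rare,
                     length(unique(fams[cnt >= 1 & cnt <= 5])))
  }
})

test_that("novelty summary handles the zero case and rejects empty input", {
  ref <- make_ref("family", "F", 100L)
  g <- make_genomes(rep("d__B;p__P;c__C;o__O;f__F", 4))
  s <- novelty_summary(g, ref, "family")
  expect_equal(s$pct_combined, 0)
  expect_equal(s$n_genomes_novel + s$n_genomes_rare, 0L)
  expect_error(novelty_summary(g[0, ], ref), "empty")
})

test_that("percentage rounding is half-up at two decimals", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(65.885, 2), 65.89)
  expect_equal(round_half_up(28.85, 1), 28.9)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(100 * 340 / 516, 2), 65.89)
  expect_equal(round_half_up(100 * 132 / 516, 2), 25.58)
})

test_that("database enrichment divides by the reference count or is undefined", {
  ref <- make_ref(rep("order", 2), c("OrdA", "OrdZero"), c(40L, 0L))
  expect_equal(database_enrichment("OrdA", 10, ref), 25.0)
  expect_equal(database_enrichment("OrdA", 0, ref), 0.0)
  und <- database_enrichment("OrdZero", 7, ref)
  expect_true(is.na(und))
  expect_match(attr(und, "reason"), "novel order")
  expect_error(database_enrichment("OrdA", -1, ref), "non-negative")
})

test_that("mean RED averages the supplied values and counts the missing", {
  g <- make_genomes(rep("d__B;p__P;c__C;o__O;f__F", 4),
                    red = c(0.70, 0.80, NA, NA))
  m <- mean_red(g)
  expect_equal(as.numeric(m), 0.75)
  expect_equal(attr(m, "n_used"), 2L)
  expect_equal(attr(m, "n_missing"), 2L)
  g2 <- make_genomes(rep("d__B;p__P;c__C;o__O;f__F", 2),
                     red = c(0.76, 0.76))
  expect_equal(as.numeric(mean_red(g2)), 0.76)
  g3 <- make_genomes("d__B;p__P;c__C;o__O;f__F", red = NA_real_)
  expect_error(mean_red(g3), "no RED")
  expect_equal(red_family_median, 0.77)
})

test_that("water genomes partition into shared and specific families", {
  sed <- make_genomes(paste0("d__B;p__P;c__C;o__O;f__F", 1:3))
  wat_sub <- make_genomes(paste0("d__B;p__P;c__C;o__O;f__F", c(1, 2, 2)),
                          habitat = "water", ids = paste0("w", 1:3))
  p <- shared_family_partition(sed, wat_sub)
  expect_equal(p$n_water_specific, 0L)
  expect_equal(p$n_water_shared, 3L)

  wat_dis <- make_genomes(paste0("d__B;p__P;c__C;o__O;f__G", 1:4),
                          habitat = "water", ids = paste0("w", 1:4))
  p2 <- shared_family_partition(sed, wat_dis)
  expect_equal(p2$n_water_shared, 0L)

  # counts always partition the water collection
  set.seed(7)
  for (rep in 1:10) {
    wfam <- sample(c(paste0("F", 1:3), paste0("G", 1:3)), 8, replace = TRUE)
    w <- make_genomes(paste0("d__B;p__P;c__C;o__O;f__", wfam),
                      habitat = "water", ids = paste0("w", 1:8))
    pp <- shared_family_partition(sed, w)
    expect_equal(pp$n_water_shared + pp$n_water_specific, nrow(w))
  }
})

test_that("genome admission enforces the contamination bound with a reason", {
  df <- data.frame(
    genome_id = c("ok", "dirty"), habitat = "sediment",
    taxonomy = "d__B;p__P;c__C;o__O;f__F",
    completeness = 90, contamination = c(5, 12), red = NA_real_,
    stringsAsFactors = FALSE)
  expect_message(g <- genome_collection(df), "dirty")
  expect_equal(g$genome_id, "ok")
  expect_error(suppressMessages(genome_collection(df[2, ])), "contamination")
})
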