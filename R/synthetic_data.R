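#' @title Seeded synthetic fixture generator
#'
#' @description
#' Generates the five input tables of the pipeline — genome metadata,
#' reference taxon counts, gene hits, KO annotations, transcript
#' abundances — with planted, fully known structure, plus a ground-truth
#' manifest recording every planted fact so each pipeline stage can be
#' tested against it. All taxon and genome names are synthetic. The
#' packaged headline configuration ([headline_fixture()]) encodes the
#' community composition of a stratified sulfidic spring survey: 516
#' sediment genomes (132 in novel and 208 in rare families, spread over 97
#' novel and 113 rare family names), 149 of them with at least one
#' reductive or disproportionating sulfur capability, and 114 water
#' genomes (62 in sediment-shared families, 52 water-specific, 59 with at
#' least one oxidative capability).
#'
#' @name synthetic_data
NULL

FIXTURE_SAMPLES <- c("morning", "afternoon", "evening")

distribute_integer <- function(total, n) {
  # deterministic integer split: first (total mod n) shares get one extra
  if (n == 0L) return(integer(0))
  q <- total %/% n
  r <- total %% n
  c(rep(q + 1L, r), rep(q, n - r))
}

#' Build a fixture configuration
#'
#' @param seed integer seed driving every random draw (reference counts,
#'   slot shuffles, bit scores, QC metrics).
#' @param families data frame with columns `name`, `status` (novel / rare /
#'   abundant), `order`, `class`, `phylum`, `n_sediment`, `n_water`.
#' @param gene_plants list of `list(habitat, slots, genes)` entries: the
#'   listed gene symbols are added to the genomes occupying those habitat
#'   slots (slot = index within habitat after the seeded shuffle of family
#'   assignments; gene plants address slots directly).
#' @param capability_plants list of `list(habitat, slots, capability)`
#'   entries; at generation time the rule engine is run and every planted
#'   capability must come out as an active call, otherwise generation
#'   aborts naming the conflict (e.g. a Dsr plant on an excluded phylum).
#' @param tpm_plan named list `gene group -> per-sample integer TPM total`,
#'   distributed over the sediment genomes carrying the group's genes.
#' @param n_noise_hits number of sub-threshold decoy hit rows (scores
#'   below 100, removed by the default filter).
#' @param ruleset rule set used for generation-time verification.
#' @return a `fixture_config` object.
#' @export
fixture_config <- function(seed, families, gene_plants = list(),
                           capability_plants = list(),
                           tpm_plan = list(), n_noise_hits = 0L,
                           ruleset = default_ruleset()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  req <- c("name", "status", "order", "class", "phylum",
           "n_sediment", "n_water")
  stopifnot(is.data.frame(families), all(req %in% names(families)))
  if (anyDuplicated(families$name)) {
    stop("family roster names must be unique", call. = FALSE)
  }
  if (any(families$n_sediment < 0L | families$n_water < 0L)) {
    stop("family genome counts must be non-negative", call. = FALSE)
  }
  if (!all(families$status %in% c("novel", "rare", "abundant"))) {
    stop("family status must be novel, rare, or abundant", call. = FALSE)
  }
  for (p in capability_plants) {
    if (!p[[3]] %in% names(ruleset)) {
      stop("capability plant references unknown capability: ", p[[3]],
           call. = FALSE)
    }
  }
  vocab <- sulfur_gene_vocabulary()
  for (p in gene_plants) {
    unknown <- setdiff(p[[3]], vocab)
    if (length(unknown) > 0L) {
      stop("gene plant references unknown symbol(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), families = families,
                 gene_plants = gene_plants,
                 capability_plants = capability_plants,
                 tpm_plan = tpm_plan, n_noise_hits = as.integer(n_noise_hits),
                 ruleset = ruleset),
            class = "fixture_config")
}

# ---- headline configuration ------------------------------------------------

headline_family_roster <- function() {
  # sediment novelty composition: 97 novel families holding 132 genomes,
  # 113 rare (LRD) families holding 208, abundant families holding the
  # remaining 176; water: 62 genomes in sediment-shared (abundant)
  # families, 52 in water-specific families.
  fam <- function(name, status, n_sed, n_wat) {
    data.frame(name = name, status = status, n_sediment = n_sed,
               n_water = n_wat, stringsAsFactors = FALSE)
  }
  novel <- fam(sprintf("ZNF-%03d", 1:97), "novel",
               c(rep(2L, 35), rep(1L, 62)), 0L)
  lrd <- fam(sprintf("FamL%03d", 1:113), "rare",
             c(rep(2L, 95), rep(1L, 18)), 0L)
  abund <- fam(sprintf("FamA%03d", 1:56), "abundant",
               c(rep(4L, 8), rep(3L, 48)),
               c(rep(2L, 31), rep(0L, 25)))
  wspec <- fam(sprintf("FamW%03d", 1:29), "abundant",
               0L, c(rep(2L, 23), rep(1L, 6)))

  # small orders (novel + rare families; every order ends up with <= 5
  # study genomes): 210 families over 206 orders, the first 4 orders
  # holding 2 families each
  small <- rbind(novel, lrd)
  k <- seq_len(nrow(small))
  small$order_idx <- ifelse(k <= 8L, (k + 1L) %/% 2L, k - 4L)
  small$order <- sprintf("O_s%03d", small$order_idx)

  # big orders (> 5 study genomes), greedily packed so each order clears
  # the size-rule boundary; their families become the family-level groups
  big <- rbind(abund, wspec)
  sizes <- big$n_sediment + big$n_water
  order_idx <- integer(nrow(big))
  cur <- 1L
  acc <- 0L
  for (i in seq_len(nrow(big))) {
    order_idx[i] <- cur
    acc <- acc + sizes[i]
    if (acc >= 6L && i < nrow(big)) {
      cur <- cur + 1L
      acc <- 0L
    }
  }
  # if the trailing order fell short of the boundary, merge it backwards
  last <- order_idx == max(order_idx)
  if (sum(sizes[last]) <= 5L && max(order_idx) > 1L) {
    order_idx[last] <- max(order_idx) - 1L
  }
  big$order_idx <- order_idx
  big$order <- sprintf("O_b%03d", big$order_idx)

  fams <- rbind(small, big)
  ords <- unique(fams$order)
  ord_seq <- match(fams$order, ords)
  phyl_idx <- ((ord_seq - 1L) %% 30L) + 1L
  fams$phylum <- sprintf("Phylum%02d", phyl_idx)
  fams$class <- sprintf("Cls%02d_%d", phyl_idx, ((ord_seq - 1L) %/% 30L) + 1L)
  fams$order_idx <- NULL
  rownames(fams) <- NULL
  fams
}

headline_gene_plants <- function() {
  list(
    # tetrathionate reduction: 73 Otr, 68 complete TtrABC, overlap 36
    list("sediment", 1:73, "Otr"),
    list("sediment", 38:105, c("TtrA", "TtrB", "TtrC")),
    # 18 canonical sulfate reducers
    list("sediment", 106:123,
         c("Sat", "AprA", "AprB", "QmoA", "QmoB", "QmoC",
           "DsrA", "DsrB", "DsrC")),
    # 104 Asr genomes; a subset also carries the adjacent Hdr locus
    list("sediment", 20:123, c("AsrA", "AsrB", "AsrC")),
    list("sediment", 20:60, c("HdrA", "HdrB", "HdrC")),
    # 8 Dsr-only sulfite reducers (membrane module, no sulfate genes)
    list("sediment", 124:131,
         c("DsrA", "DsrB", "DsrC", "DsrK", "DsrM", "DsrJ")),
    # 20 polysulfide reducers
    list("sediment", 130:149, c("PsrA", "PsrB", "PsrC")),
    # 11 PhsABC genomes: 5 with SoeABC (disproportionation), 2 with Asr
    # (thiosulfate reduction), 4 with neither
    list("sediment", c(1:9, 40, 41), c("PhsA", "PhsB", "PhsC")),
    list("sediment", 1:5, c("SoeA", "SoeB", "SoeC")),
    # 14 rhodanese-route disproportionators (Sat+AprAB without Qmo)
    list("sediment", 42:55, c("Rhd", "Sat", "AprA", "AprB")),
    # 119 sulfurhydrogenase genomes; 150..160 carry nothing else, so the
    # flag direction must not inflate the reductive total
    list("sediment", 20:127, c("HydA", "HydB", "HydC", "HydD")),
    list("sediment", 150:160, c("ShyA", "ShyB", "ShyC", "ShyD")),
    # inert decoys: accessory symbols no shipped rule requires
    list("sediment", 200:300, c("DsrD", "DsrE", "DsrF", "DsrH")),
    # water community: oxidative union is slots 1..59
    list("water", 1:39, "Sqr"),
    list("water", 1:2, c("DsrA", "DsrB", "DsrC")),
    list("water", 1:14,
         c("SoxA", "SoxX", "SoxB", "SoxY", "SoxZ", "SoxC", "SoxD")),
    list("water", 38:59, c("SoeA", "SoeB", "SoeC")),
    list("water", 52:59, "TsdA"),
    list("water", 58:59, "TetH")
  )
}

headline_capability_plants <- function() {
  list(
    list("sediment", 106:123, "sulfate_reduction"),
    list("sediment", 20:123, "sulfite_reduction_asr"),
    list("sediment", 124:131, "sulfite_reduction_dsr"),
    list("sediment", 130:149, "polysulfide_reduction"),
    list("sediment", 1:105, "tetrathionate_reduction"),
    list("sediment", c(40, 41), "thiosulfate_reduction"),
    list("sediment", 1:5, "thiosulfate_disproportionation_phs"),
    list("sediment", 42:55, "thiosulfate_disproportionation_rhd"),
    list("sediment", c(20:127, 150:160), "sulfurhydrogenase"),
    list("water", 1:39, "sulfide_oxidation"),
    list("water", 1:14, "sox_complete"),
    list("water", 1:2, "sulfur_oxidation_rdsr"),
    list("water", 38:59, "sulfite_oxidation"),
    list("water", 52:59, "thiosulfate_oxidation_tetrathionate"),
    list("water", 58:59, "tetrathionate_hydrolysis")
  )
}

#' The packaged headline fixture configuration
#'
#' Encodes the printed community composition the package's worked example
#' reproduces: 516 sediment genomes with 132 in novel and 208 in rare
#' families (97 novel / 113 rare family names), 149 sediment genomes with
#' at least one reductive or disproportionating capability (18 sulfate,
#' 104 Asr, 8 Dsr-only, 20 Psr, 11 Phs, 73 Otr and 68 Ttr with 36 in
#' both), 114 water genomes (62 sediment-shared, 52 water-specific, 59
#' oxidative), and a transcript plan with an Asr:Dsr group ratio of 4.
#'
#' @param seed integer seed (default 20220116). The planted counts are
#'   integer facts independent of the seed; the seed only varies reference
#'   counts within their status band, slot shuffles, bit scores and QC
#'   metrics.
#' @return a `fixture_config`.
#' @export
headline_fixture <- function(seed = 20220116) {
  fixture_config(
    seed = seed,
    families = headline_family_roster(),
    gene_plants = headline_gene_plants(),
    capability_plants = headline_capability_plants(),
    tpm_plan = list(asr_system = 400L, dsr_system = 100L,
                    sulfate_reduction_genes = 60L, phs_system = 12L,
                    psr_system = 24L, tetrathionate_reduction_genes = 48L,
                    rhodanese = 10L, sulfurhydrogenases = 80L,
                    unassigned = 30L),
    n_noise_hits = 400L
  )
}

# ---- generation ------------------------------------------------------------

#' Generate the five input tables from a fixture configuration
#'
#' The generator is seed-deterministic: the same configuration and seed
#' produce byte-identical tables. At generation time the capability rule
#' engine is run over the planted gene sets and every planted capability
#' must be an active call; a contradictory plant (requirement unmet,
#' suppressed, or vetoed by a taxon exclusion) aborts with an error naming
#' the genome and capability.
#'
#' @param config a [fixture_config()].
#' @param out_dir if non-`NULL`, the tables and a YAML manifest are also
#'   written there as TSVs.
#' @param seed optional seed override.
#' @return list with `genomes` (admitted collection), `ref_counts_df`,
#'   `hits`, `ko`, `tpm` (data frames) and `manifest` (ground truth:
#'   planted statuses, capability slots, expected engine calls, lineage
#'   pathway matrix, TPM plan).
#' @export
generate_fixture <- function(config, out_dir = NULL, seed = config$seed) {
  stopifnot(inherits(config, "fixture_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  fams <- config$families
  # reference counts: rare families draw uniformly from the 1..5 band,
  # abundant from 6..200; novel families are simply absent from the table
  fams$ref_count <- ifelse(
    fams$status == "rare", sample(1:5, nrow(fams), replace = TRUE),
    ifelse(fams$status == "abundant",
           sample(6:200, nrow(fams), replace = TRUE), NA_integer_))
  ords <- unique(fams[, c("order", "class", "phylum")])
  ref_df <- rbind(
    data.frame(rank = "family",
               taxon = fams$name[fams$status != "novel"],
               count = fams$ref_count[fams$status != "novel"],
               stringsAsFactors = FALSE),
    data.frame(rank = "order", taxon = ords$order,
               count = ifelse(grepl("^O_s", ords$order), 2L, 80L),
               stringsAsFactors = FALSE),
    data.frame(rank = "class", taxon = unique(ords$class), count = 50L,
               stringsAsFactors = FALSE),
    data.frame(rank = "phylum", taxon = unique(ords$phylum), count = 100L,
               stringsAsFactors = FALSE)
  )

  # genome roster: family labels shuffled over habitat slots so novelty
  # strata and capability slots decorrelate
  slot_families <- function(habitat_col) {
    labels <- rep(fams$name, fams[[habitat_col]])
    if (length(labels) == 0L) return(character(0))
    labels[sample(length(labels))]
  }
  sed_fam <- slot_families("n_sediment")
  wat_fam <- slot_families("n_water")
  n_sed <- length(sed_fam)
  n_wat <- length(wat_fam)

  mk_genomes <- function(fam_vec, habitat, prefix, red_pair) {
    n <- length(fam_vec)
    if (n == 0L) return(NULL)
    fi <- match(fam_vec, fams$name)
    data.frame(
      genome_id = sprintf("%s_%04d", prefix, seq_len(n)),
      habitat = habitat,
      taxonomy = paste0("d__Bacteria;p__", fams$phylum[fi],
                        ";c__", fams$class[fi],
                        ";o__", fams$order[fi],
                        ";f__", fam_vec),
      completeness = round(stats::runif(n, 70, 99), 2),
      contamination = round(stats::runif(n, 0, 9.5), 2),
      red = rep_len(red_pair, n),
      stringsAsFactors = FALSE)
  }
  # alternating RED values average to 0.76 (sediment) and 0.85 (water)
  genome_df <- rbind(mk_genomes(sed_fam, "sediment", "ZS", c(0.71, 0.81)),
                     mk_genomes(wat_fam, "water", "ZW", c(0.80, 0.90)))
  genomes <- genome_collection(genome_df)

  slot_id <- function(habitat, slots) {
    prefix <- if (habitat == "sediment") "ZS" else "ZW"
    n <- if (habitat == "sediment") n_sed else n_wat
    if (any(slots < 1L | slots > n)) {
      stop("plant addresses slot outside the ", habitat, " roster",
           call. = FALSE)
    }
    sprintf("%s_%04d", prefix, slots)
  }

  # gene hit table: planted hits score in [150, 400]; decoy noise scores
  # in [20, 99.5] sit below the default threshold
  hit_rows <- list()
  for (p in config$gene_plants) {
    ids <- slot_id(p[[1]], p[[2]])
    combo <- expand.grid(genome_id = ids, gene_symbol = p[[3]],
                         stringsAsFactors = FALSE)
    combo$bit_score <- round(stats::runif(nrow(combo), 150, 400), 1)
    hit_rows[[length(hit_rows) + 1L]] <- combo
  }
  if (config$n_noise_hits > 0L) {
    noise <- data.frame(
      genome_id = sample(genomes$genome_id, config$n_noise_hits,
                         replace = TRUE),
      gene_symbol = sample(sulfur_gene_vocabulary(), config$n_noise_hits,
                           replace = TRUE),
      bit_score = round(stats::runif(config$n_noise_hits, 20, 99.5), 1),
      stringsAsFactors = FALSE)
    hit_rows[[length(hit_rows) + 1L]] <- noise
  }
  hits <- do.call(rbind, c(hit_rows, list(
    data.frame(genome_id = character(0), gene_symbol = character(0),
               bit_score = numeric(0), stringsAsFactors = FALSE))))
  rownames(hits) <- NULL

  # generation-time verification: every planted capability must be called
  presence <- gene_presence(hits, threshold = 100)
  calls <- call_genomes(presence, genomes, config$ruleset)
  active_key <- paste(calls$genome_id[calls$active],
                      calls$capability[calls$active])
  plant_df <- do.call(rbind, lapply(config$capability_plants, function(p) {
    data.frame(genome_id = slot_id(p[[1]], p[[2]]), capability = p[[3]],
               stringsAsFactors = FALSE)
  })) %||% data.frame(genome_id = character(0), capability = character(0))
  missing <- !(paste(plant_df$genome_id, plant_df$capability) %in% active_key)
  if (any(missing)) {
    bad <- plant_df[missing, , drop = FALSE][1, ]
    sup <- calls$suppressed_by[calls$genome_id == bad$genome_id &
                                 calls$capability == bad$capability]
    why <- if (length(sup) == 1L && !is.na(sup)) {
      paste0("suppressed by ", sup)
    } else {
      "requirement unmet or vetoed by a taxon exclusion"
    }
    stop("contradictory plant: capability '", bad$capability,
         "' is not an active call on genome ", bad$genome_id, " (", why,
         ")", call. = FALSE)
  }

  # KO table: per lineage group, pathways are planted present (best member
  # at the threshold) or absent by a deterministic integer pattern
  groups <- build_lineage_groups(genomes)
  pathways <- load_pathway_defs()
  planted <- matrix(FALSE, nrow(groups), length(pathways),
                    dimnames = list(paste(groups$rank, groups$taxon,
                                          sep = ":"),
                                    names(pathways)))
  ko_rows <- list()
  for (i in seq_len(nrow(groups))) {
    ids <- groups$genome_ids[[i]]
    for (j in seq_along(pathways)) {
      pw <- pathways[[j]]
      n_ko <- length(pw$kos)
      present <- ((i * 7L + j * 3L) %% 5L) < 2L
      planted[i, j] <- present
      n_best <- if (present) ceiling(pw$threshold * n_ko) else {
        floor(0.4 * n_ko)
      }
      n_rest <- floor(0.4 * n_ko)
      for (k in seq_along(ids)) {
        n_give <- if (k == 1L) n_best else n_rest
        if (n_give > 0L) {
          ko_rows[[length(ko_rows) + 1L]] <- data.frame(
            genome_id = ids[k], ko = pw$kos[seq_len(n_give)],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ko <- do.call(rbind, ko_rows)
  rownames(ko) <- NULL

  # TPM table: each planned per-sample group total is split integrally
  # over the sediment genomes carrying the group's genes; the unassigned
  # plan rides on a symbol outside every group
  groups_map <- default_gene_groups()
  sed_ids <- genomes$genome_id[genomes$habitat == "sediment"]
  tpm_rows <- list()
  for (g in names(config$tpm_plan)) {
    total <- config$tpm_plan[[g]]
    if (g == "unassigned") {
      syms <- "SoeA"   # in the vocabulary, assigned to no default group
    } else {
      syms <- groups_map[[g]]
      if (is.null(syms)) stop("tpm plan names unknown group: ", g,
                              call. = FALSE)
    }
    carriers <- sed_ids[vapply(sed_ids, function(id)
      any(syms %in% genes_of(presence, id)), logical(1))]
    if (length(carriers) == 0L) next
    share <- distribute_integer(total, length(carriers))
    first_gene <- vapply(carriers, function(id)
      intersect(syms, genes_of(presence, id))[1], character(1))
    for (s in FIXTURE_SAMPLES) {
      tpm_rows[[length(tpm_rows) + 1L]] <- data.frame(
        sample_id = s, genome_id = carriers, gene_symbol = first_gene,
        tpm = share, stringsAsFactors = FALSE)
    }
  }
  tpm <- do.call(rbind, c(tpm_rows, list(
    data.frame(sample_id = character(0), genome_id = character(0),
               gene_symbol = character(0), tpm = numeric(0),
               stringsAsFactors = FALSE))))
  tpm <- tpm[tpm$tpm > 0, , drop = FALSE]
  rownames(tpm) <- NULL

  manifest <- list(
    seed = as.integer(seed),
    n_sediment = n_sed,
    n_water = n_wat,
    family_status = stats::setNames(fams$status, fams$name),
    capability_plants = plant_df,
    expected_calls = calls,
    planted_pathways = planted,
    tpm_plan = config$tpm_plan,
    counts = list(
      novel_families = length(unique(sed_fam[
        fams$status[match(sed_fam, fams$name)] == "novel"])),
      rare_families = length(unique(sed_fam[
        fams$status[match(sed_fam, fams$name)] == "rare"])),
      novel_genomes = sum(fams$status[match(sed_fam, fams$name)] == "novel"),
      rare_genomes = sum(fams$status[match(sed_fam, fams$name)] == "rare")
    )
  )

  out <- list(genomes = genomes, ref_counts_df = ref_df, hits = hits,
              ko = ko, tpm = tpm, manifest = manifest)
  if (!is.null(out_dir)) write_fixture(out, out_dir)
  out
}

#' Write a generated fixture to a directory
#'
#' @param fixture output of [generate_fixture()].
#' @param out_dir target directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genomes = file.path(out_dir, "genome_metadata.tsv"),
    ref_counts = file.path(out_dir, "reference_counts.tsv"),
    hits = file.path(out_dir, "gene_hits.tsv"),
    ko = file.path(out_dir, "ko_annotations.tsv"),
    tpm = file.path(out_dir, "transcript_abundance.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  g <- fixture$genomes[, c("genome_id", "habitat", "taxonomy",
                           "completeness", "contamination", "red")]
  write_tsv_plain(g, paths[["genomes"]])
  write_tsv_plain(fixture$ref_counts_df, paths[["ref_counts"]])
  write_tsv_plain(fixture$hits, paths[["hits"]])
  write_tsv_plain(fixture$ko, paths[["ko"]])
  write_tsv_plain(fixture$tpm, paths[["tpm"]])
  man <- fixture$manifest
  yaml::write_yaml(list(
    seed = man$seed, n_sediment = man$n_sediment, n_water = man$n_water,
    counts = man$counts,
    family_status = as.list(man$family_status),
    capability_plants = lapply(seq_len(nrow(man$capability_plants)),
                               function(i) as.list(man$capability_plants[i, ])),
    tpm_plan = man$tpm_plan
  ), paths[["manifest"]])
  invisible(paths)
}
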