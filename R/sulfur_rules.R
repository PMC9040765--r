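#' @title Declarative sulfur-cycling capability rules
#'
#' @description
#' Capabilities (sulfate reduction, Asr/Dsr sulfite reduction, polysulfide,
#' thiosulfate and tetrathionate reduction, thiosulfate disproportionation,
#' and the oxidative systems) are encoded as boolean requirement
#' expressions over per-genome gene presence sets, evaluated together with
#' taxonomy context. Rules are data: a YAML file with combinators
#' `all` / `any` / `at_least {k, of}` / `not`, taxon exclusions, and
#' capability-level suppression. The shipped default set lives in
#' `system.file("extdata", "sulfur_rules.yaml", package = "sulfurMAGs")`.
#'
#' @name sulfur_rules
NULL

RULE_DIRECTIONS <- c("reduction", "disproportionation", "oxidation", "flag")

# ---- expression handling ---------------------------------------------------

expr_symbols <- function(node) {
  if (is.character(node)) return(node)
  if (!is.list(node) || length(node) != 1L) {
    stop("malformed rule expression node", call. = FALSE)
  }
  op <- names(node)
  body <- node[[1]]
  switch(op,
    all = ,
    any = unlist(lapply(if (is.list(body)) body else as.list(body),
                        expr_symbols), use.names = FALSE),
    at_least = as.character(body$of),
    not = expr_symbols(body),
    context = character(0),
    stop("unknown rule combinator '", op, "'", call. = FALSE)
  )
}

# Evaluate an expression against a gene set. Returns list(sat, evidence)
# where evidence is the minimal satisfying subset found by a deterministic
# left-to-right walk: `all` unions child evidence, `any` takes the first
# satisfied branch, `at_least` the first k present members in list order,
# `not` and `context` contribute no evidence.
eval_expr <- function(node, genes, context) {
  if (is.character(node) && length(node) == 1L) {
    present <- node %in% genes
    return(list(sat = present, evidence = if (present) node else character(0)))
  }
  op <- names(node)
  body <- node[[1]]
  switch(op,
    all = {
      kids <- if (is.list(body)) body else as.list(body)
      ev <- character(0)
      for (k in kids) {
        r <- eval_expr(k, genes, context)
        if (!r$sat) return(list(sat = FALSE, evidence = character(0)))
        ev <- c(ev, r$evidence)
      }
      list(sat = TRUE, evidence = unique(ev))
    },
    any = {
      kids <- if (is.list(body)) body else as.list(body)
      for (k in kids) {
        r <- eval_expr(k, genes, context)
        if (r$sat) return(r)
      }
      list(sat = FALSE, evidence = character(0))
    },
    at_least = {
      of <- as.character(body$of)
      k <- as.integer(body$k)
      hit <- of[of %in% genes]
      if (length(hit) >= k) {
        list(sat = TRUE, evidence = hit[seq_len(k)])
      } else {
        list(sat = FALSE, evidence = character(0))
      }
    },
    not = {
      r <- eval_expr(body, genes, context)
      list(sat = !r$sat, evidence = character(0))
    },
    context = {
      list(sat = isTRUE(context[[as.character(body)]]),
           evidence = character(0))
    },
    stop("unknown rule combinator '", op, "'", call. = FALSE)
  )
}

expr_uses_context <- function(node) {
  if (is.character(node)) return(FALSE)
  op <- names(node)
  body <- node[[1]]
  switch(op,
    context = TRUE,
    at_least = FALSE,
    not = expr_uses_context(body),
    all = ,
    any = {
      kids <- if (is.list(body)) body else as.list(body)
      any(vapply(kids, expr_uses_context, logical(1)))
    },
    FALSE
  )
}

# ---- rule set loading ------------------------------------------------------

#' Load and validate a capability rule set
#'
#' Validation happens at load time, not evaluation time: every referenced
#' gene symbol must be in the shipped vocabulary, directions must be one of
#' reduction / disproportionation / oxidation / flag, rule names must be
#' unique, and capability-suppression references must resolve without
#' cycles.
#'
#' @param path YAML rule file (default: the shipped rule set).
#' @return a `capability_ruleset`: named list of rules in file order.
#' @export
load_ruleset <- function(path = default_ruleset_path()) {
  raw <- yaml::read_yaml(path)
  rules <- raw$rules
  if (is.null(rules) || length(rules) == 0L) {
    stop("rule file contains no rules: ", path, call. = FALSE)
  }
  nm <- vapply(rules, function(r) r$name %||% "", character(1))
  if (any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("rules must have unique non-empty names", call. = FALSE)
  }
  vocab <- sulfur_gene_vocabulary()
  for (r in rules) {
    if (!(r$direction %||% "") %in% RULE_DIRECTIONS) {
      stop("rule '", r$name, "': invalid direction '", r$direction, "'",
           call. = FALSE)
    }
    syms <- expr_symbols(r$require)
    unknown <- setdiff(syms, vocab)
    if (length(unknown) > 0L) {
      stop("rule '", r$name, "' references unknown gene symbol(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (ann in r$annotate %||% list()) {
      unknown <- setdiff(expr_symbols(ann), vocab)
      if (length(unknown) > 0L) {
        stop("rule '", r$name, "' annotation references unknown symbol(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
    bad_excl <- setdiff(r$exclude_capabilities %||% character(0), nm)
    if (length(bad_excl) > 0L) {
      stop("rule '", r$name, "' excludes unknown capability: ",
           paste(bad_excl, collapse = ", "), call. = FALSE)
    }
  }
  rules <- stats::setNames(rules, nm)
  # reject cyclic suppression
  visiting <- character(0)
  visit <- function(n) {
    if (n %in% visiting) {
      stop("cyclic capability_exclusions involving '", n, "'", call. = FALSE)
    }
    visiting <<- c(visiting, n)
    for (dep in rules[[n]]$exclude_capabilities %||% character(0)) visit(dep)
    visiting <<- setdiff(visiting, n)
  }
  for (n in nm) visit(n)
  structure(rules, path = path, class = "capability_ruleset")
}

#' Path of the shipped default rule file
#' @return file path.
#' @export
default_ruleset_path <- function() {
  system.file("extdata", "sulfur_rules.yaml", package = "sulfurMAGs",
              mustWork = TRUE)
}

#' Shipped default rule set (cached per session)
#' @return a `capability_ruleset`.
#' @export
default_ruleset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_ruleset()
    cache
  }
})

# ---- evaluation ------------------------------------------------------------

taxonomy_names <- function(taxonomy) {
  if (is.null(taxonomy)) return(character(0))
  if (inherits(taxonomy, "ranked_taxonomy")) return(unname(taxonomy$ranks))
  as.character(taxonomy)
}

#' Evaluate one rule on one genome
#'
#' A call is emitted iff the requirement is satisfied and no taxon
#' exclusion matches any rank name of the genome's lineage. The evidence is
#' the minimal satisfying gene subset under a deterministic left-to-right
#' expression walk.
#'
#' @param rule one rule from a [load_ruleset()] rule set.
#' @param genes character vector of gene symbols present in the genome.
#' @param taxonomy the genome's lineage: a `ranked_taxonomy` or a character
#'   vector of rank names (optional; rules with taxon exclusions need it).
#' @param context named logical list of context flags (see the rule file;
#'   `other_oxidative` is set by [call_genome()]).
#' @return a capability call (list) or `NULL` when the rule does not fire.
#' @export
evaluate_rule <- function(rule, genes, taxonomy = NULL,
                          context = list(other_oxidative = FALSE)) {
  tx <- taxonomy_names(taxonomy)
  excl <- intersect(rule$exclude_taxa %||% character(0), tx)
  if (length(excl) > 0L) return(NULL)
  r <- eval_expr(rule$require, genes, context)
  if (!r$sat) return(NULL)
  annotations <- character(0)
  for (ann_name in names(rule$annotate %||% list())) {
    if (eval_expr(rule$annotate[[ann_name]], genes, context)$sat) {
      annotations <- c(annotations, ann_name)
    }
  }
  list(capability = rule$name, direction = rule$direction,
       evidence = r$evidence, annotations = annotations)
}

#' Evaluate a full rule set on one genome
#'
#' Rules are evaluated in file order; rules using the `other_oxidative`
#' context node are then re-evaluated with the flag set when the genome has
#' at least one other active oxidation-direction call. Capability
#' suppression (`exclude_capabilities`) is applied after evaluation:
#' suppressed calls are retained with `suppressed_by` recorded and
#' `active = FALSE`, so the "excluding duplicate hits" step stays auditable.
#'
#' @param genome_id genome identifier.
#' @param genes gene symbols present in the genome.
#' @param taxonomy the genome's lineage (see [evaluate_rule()]).
#' @param ruleset a `capability_ruleset`.
#' @return data frame: genome_id, capability, direction, active, evidence
#'   (comma-joined), suppressed_by, annotations; one row per emitted call.
#' @export
call_genome <- function(genome_id, genes, taxonomy = NULL,
                        ruleset = default_ruleset()) {
  ctx0 <- list(other_oxidative = FALSE)
  calls <- list()
  for (rule in ruleset) {
    res <- evaluate_rule(rule, genes, taxonomy, ctx0)
    if (!is.null(res)) calls[[rule$name]] <- res
  }
  # second pass for context-dependent rules: does any OTHER rule give an
  # active oxidative call?
  for (rule in ruleset) {
    if (!expr_uses_context(rule$require)) next
    others <- calls[setdiff(names(calls), rule$name)]
    other_ox <- any(vapply(others, function(cc) cc$direction == "oxidation",
                           logical(1)))
    res <- evaluate_rule(rule, genes, taxonomy,
                         list(other_oxidative = other_ox))
    if (is.null(res)) calls[[rule$name]] <- NULL else calls[[rule$name]] <- res
  }
  # suppression, in rule-file order (cycles rejected at load)
  suppressed_by <- stats::setNames(rep(NA_character_, length(calls)),
                                   names(calls))
  for (nm in names(ruleset)) {
    if (!nm %in% names(calls)) next
    for (ex in ruleset[[nm]]$exclude_capabilities %||% character(0)) {
      if (ex %in% names(calls) && is.na(suppressed_by[[ex]])) {
        suppressed_by[[nm]] <- ex
        break
      }
    }
  }
  if (length(calls) == 0L) return(empty_calls_df())
  data.frame(
    genome_id = genome_id,
    capability = names(calls),
    direction = vapply(calls, `[[`, character(1), "direction"),
    active = unname(is.na(suppressed_by)),
    evidence = vapply(calls, function(cc)
      paste(cc$evidence, collapse = ","), character(1)),
    suppressed_by = unname(suppressed_by),
    annotations = vapply(calls, function(cc)
      paste(cc$annotations, collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

empty_calls_df <- function() {
  data.frame(genome_id = character(0), capability = character(0),
             direction = character(0), active = logical(0),
             evidence = character(0), suppressed_by = character(0),
             annotations = character(0), stringsAsFactors = FALSE)
}

#' Evaluate a rule set over a genome collection
#'
#' @param presence a `gene_presence` object (see [load_hits()]).
#' @param genomes a genome collection data frame (see
#'   [genome_collection()]); supplies lineage context per genome. Genomes
#'   with no retained hits simply produce no calls.
#' @param ruleset a `capability_ruleset`.
#' @return combined calls data frame (columns as [call_genome()]), with the
#'   rule-set capability names in attribute `capabilities`.
#' @export
call_genomes <- function(presence, genomes, ruleset = default_ruleset()) {
  unknown <- setdiff(names(presence), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop("gene hits reference unknown genome id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  rank_mat <- as.matrix(genomes[, TAXONOMY_RANKS])
  out <- vector("list", nrow(genomes))
  for (i in seq_len(nrow(genomes))) {
    gid <- genomes$genome_id[i]
    genes <- genes_of(presence, gid)
    if (length(genes) == 0L) next
    out[[i]] <- call_genome(gid, genes, rank_mat[i, ], ruleset)
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(empty_calls_df())))
  attr(res, "capabilities") <- names(ruleset)
  res
}

#' Summarize capability calls per habitat
#'
#' Active calls only (suppressed calls are excluded from all counts).
#' `reductive_any` counts genomes with at least one active call of
#' direction reduction or disproportionation; `flag` rules (the
#' sulfurhydrogenases, whose respiratory role is unresolved) are never
#' counted. `oxidative_any` is the analogue for oxidation.
#'
#' @param calls calls data frame from [call_genomes()].
#' @param genomes the genome collection the calls refer to.
#' @param decimals decimals for the percentage columns (half-up rounding).
#' @return list with `per_capability` and `habitat_totals` data frames.
#' @export
summarize_calls <- function(calls, genomes, decimals = 1) {
  bad <- setdiff(calls$genome_id, genomes$genome_id)
  if (length(bad) > 0L) {
    stop("calls reference unknown genome id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  act <- calls[calls$active, , drop = FALSE]
  idx <- match(act$genome_id, genomes$genome_id)
  act$habitat <- genomes$habitat[idx]
  for (r in c("phylum", "class", "order", "family")) {
    act[[r]] <- genomes[[r]][idx]
  }
  caps <- attr(calls, "capabilities") %||% sort(unique(calls$capability))

  per_cap <- do.call(rbind, lapply(split(
    act, list(act$habitat, act$capability), drop = TRUE),
    function(d) data.frame(
      habitat = d$habitat[1], capability = d$capability[1],
      direction = d$direction[1],
      n_genomes = length(unique(d$genome_id)),
      n_phyla = length(unique(d$phylum)),
      n_classes = length(unique(d$class)),
      n_orders = length(unique(d$order)),
      n_families = length(unique(d$family)),
      stringsAsFactors = FALSE)))
  if (is.null(per_cap)) {
    per_cap <- data.frame(habitat = character(0), capability = character(0),
                          direction = character(0), n_genomes = integer(0),
                          n_phyla = integer(0), n_classes = integer(0),
                          n_orders = integer(0), n_families = integer(0),
                          stringsAsFactors = FALSE)
  } else {
    per_cap <- per_cap[order(per_cap$habitat,
                             match(per_cap$capability, caps)), ]
    rownames(per_cap) <- NULL
  }

  habitats <- sort(unique(genomes$habitat))
  totals <- do.call(rbind, lapply(habitats, function(h) {
    hg <- genomes$genome_id[genomes$habitat == h]
    n <- length(hg)
    red <- unique(act$genome_id[act$habitat == h &
                                  act$direction %in%
                                  c("reduction", "disproportionation")])
    ox <- unique(act$genome_id[act$habitat == h &
                                 act$direction == "oxidation"])
    data.frame(
      habitat = h, n_genomes = n,
      reductive_any = length(red),
      pct_reductive = round_half_up(100 * length(red) / n, decimals),
      oxidative_any = length(ox),
      pct_oxidative = round_half_up(100 * length(ox) / n, decimals),
      stringsAsFactors = FALSE)
  }))
  list(per_capability = per_cap, habitat_totals = totals)
}

#' Overlap between two capabilities
#'
#' Counts genomes with an active call for each capability, both, and their
#' union; the inclusion-exclusion identity `n_union = n_a + n_b - n_both`
#' holds by construction.
#'
#' @param calls calls data frame from [call_genomes()].
#' @param capability_a,capability_b capability names.
#' @return list `n_a`, `n_b`, `n_both`, `n_union`.
#' @export
capability_overlap <- function(calls, capability_a, capability_b) {
  caps <- attr(calls, "capabilities") %||% unique(calls$capability)
  for (cap in c(capability_a, capability_b)) {
    if (!cap %in% caps) stop("unknown capability: ", cap, call. = FALSE)
  }
  act <- calls[calls$active, , drop = FALSE]
  a <- unique(act$genome_id[act$capability == capability_a])
  b <- unique(act$genome_id[act$capability == capability_b])
  list(n_a = length(a), n_b = length(b),
       n_both = length(intersect(a, b)),
       n_union = length(union(a, b)))
}

#' Write capability calls to TSV
#'
#' @param calls calls data frame.
#' @param path output file.
#' @param provenance optional provenance comment line.
#' @return the path, invisibly.
#' @export
write_calls <- function(calls, path, provenance = NULL) {
  write_tsv_plain(calls, path, provenance)
}
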