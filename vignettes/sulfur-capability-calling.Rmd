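---
title: "Novelty classification and sulfur capability calling for MAG collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Novelty classification and sulfur capability calling for MAG collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfurMAGs)
```

## The problem

Metagenomic surveys of anoxic, sulfide-rich habitats routinely recover
hundreds of metagenome-assembled genomes (MAGs) whose lineages are poorly
represented in reference databases, and whose sulfur metabolism must be
inferred from gene content alone. The raw ingredients — a GTDB-style
taxonomy per genome, profile-HMM hits against custom sulfur-gene models,
KO annotations, transcript abundances — are produced by standard upstream
tools. What is usually *not* explicit is the decision layer: when exactly
a lineage counts as novel; which gene combinations justify calling a
genome a sulfate reducer rather than a sulfite reducer running the same
Dsr machinery; how a pathway is attributed to a lineage rather than a
genome. This package encodes that layer as data-driven, testable rules.

## Novelty and rarity

Each of the seven ranks of a taxonomy string is classified against a
reference genome-count table: **novel** with 0 reference genomes,
**rare** (a lineage of rare distribution, LRD) with 1–5, **abundant**
with more than 5. The 5-genome cutoff separates lineages effectively
unsampled on the current earth from well-characterized ones; reserving
*novel* for exactly zero keeps the three statuses a partition. Absent
taxa look up as count 0 by construction, so novelty never depends on the
completeness of the reference table's zero rows.

Unnamed trailing ranks become deterministic ZN-prefixed placeholders
(`ZNC`/`ZNO`/`ZNF`… for novel class/order/family) carrying the deepest
named parent, matching the field's convention for labeling novel
lineages; placeholders are always novel. Strings whose tokens all carry
names round-trip losslessly through parsing; strings with trailing empty
tokens (`"d__X;p__"`) are accepted but normalized, which is the one
deliberate deviation from byte-level round-tripping.

Percentages are rounded half-up (2 decimals for novelty summaries, 1 for
the habitat capability percentages), the convention that makes 340/516
print as 65.89 and 149/516 as 28.9. Reports always carry numerator and
denominator alongside any percentage. Relative evolutionary divergence
(RED) values are consumed, not computed; `mean_red()` averages the
supplied values and reports how many genomes lacked one, and the package
exposes the 0.77 reference median used to contextualize family-level
novelty.

## Gene presence

Hits are filtered at a bit-score threshold of 100, inclusive — the
semantics of hmmscan's `-T 100`, "an alignment score of at least 100" —
so a 100.0-score hit is retained and 99.9 is not. Multi-copy hits
collapse to presence/absence, since every downstream rule is boolean.
Symbols are normalized case-insensitively over a 61-symbol controlled
vocabulary plus aliases (both rhodanese EC numbers, 2.8.1.1 and 2.8.1.3,
map to the single functional symbol `Rhd`); unknown symbols are collected
into a rejects report rather than silently kept or dropped. Tree-based
vetting of candidate hits is upstream of this package; an optional
`confirmed` column lets users of the real workflow feed only vetted hits.

## The capability rule set

Rules live in `inst/extdata/sulfur_rules.yaml` — data, not code — with
`all` / `any` / `at_least(k of S)` / `not` combinators. Choices that the
gene lists alone do not fix, and the rationale for each:

* **DsrKMJOP completeness.** The membrane module is named as a system
  without subunit criteria; the shipped rule demands at least 3 of the 5
  subunits alongside DsrABC — tolerant of annotation dropout while still
  requiring a membrane complex. The cutoff is editable in the rule file.
* **Dsr directionality.** No single marker separates reductive from
  oxidative Dsr. The reductive call is vetoed in lineages known to run
  the system oxidatively (Proteobacteria, Nitrospira/Nitrospirota,
  Chlorobiaceae — matched at any rank), and the oxidative reverse-Dsr
  call requires co-occurring sulfide-oxidation genes and the *absence*
  of the full sulfate-reduction complement. `DsrD`/`DsrEFH` are in the
  vocabulary so users can tighten rules with accessory markers.
* **Suppression, not deletion.** A genome satisfying full sulfate
  reduction also satisfies the sulfite-reduction pattern; the narrower
  call is retained with `suppressed_by` recorded and excluded from
  counts, keeping the de-duplication auditable.
* **Reversal-route sulfite oxidation.** AprAB+QmoABC+Sat read in the
  oxidative direction is only credible in an otherwise oxidative genome;
  the rule file encodes this as a context node that is true when the
  genome has another active oxidation call.
* **Sulfurhydrogenases are flags.** HydABCD/ShyABCD are reported but
  carry direction `flag` and never count toward the reductive totals,
  because their role in respiration is unresolved.
* **"Reductive" totals** count reduction *and* disproportionation
  directions, the grouping used when reductive community membership is
  summarized; tetrathionate-only genomes count as reductive even without
  downstream sulfite/thiosulfate reduction.
* **SOX completeness** means all seven of SoxXA, SoxB, SoxYZ, SoxCD, the
  configuration contrasted with partial systems.

Evidence for every call is the minimal satisfying gene subset under a
deterministic left-to-right expression walk (`any` takes its first
satisfied branch, `at_least` the first *k* present members), so evaluating
a rule on its own evidence reproduces the call — a property the test
suite checks on random genomes. For rules without exclusions, adding
genes never removes a call; the two exclusion-bearing rules are the
documented, tested exceptions.

## Lineage-level metabolism

Genomes group by order when the order has 5 or fewer study genomes and by
family within larger orders — the same 5-genome boundary as rarity, and a
partition of the collection by construction. A pathway is present in a
lineage iff at least one member genome carries ≥ 80% of the pathway's
KOs. Pooling KOs across members is deliberately not done: a lineage of
fragmentary genomes that jointly tile a pathway no genome encodes should
not be credited with it. The boundary comparison is exact (integer
cross-multiplication with the threshold scaled to 6 decimals), so 8 of 10
passes and 79 of 100 fails with no floating-point edge; no per-pathway
rounding of the KO count is applied. The shipped pathway file is an
illustrative default with synthetic K-numbers — KO lists are data
versioned independently of code, and real analyses should supply curated
lists.

## Transcription

TPM rows aggregate by gene group and phylum. Genes in no group land in an
explicit `unassigned` bucket so that, per sample, group totals conserve
the input TPM exactly. Because the upstream normalization is per-sample,
both per-sample tables and a pooled (summed) view are emitted; neither is
privileged. Ratios between group totals (e.g. Asr:Dsr) return an explicit
undefined sentinel on a zero denominator.

## What the generator emulates — and what it does not

The synthetic module plants: a family roster with chosen novelty
composition and reference counts (rare families draw their count
uniformly from 1–5, exercising the whole band); minimal satisfying gene
sets per planted capability, plus decoy accessory genes and sub-threshold
noise hits; per-lineage KO sets at controlled completeness on either side
of the 80% boundary; and integer TPM plans with exact group ratios. At
generation time the rule engine is run over the planted genomes and any
planted capability that does not come out as an active call — unmet,
suppressed, or taxon-vetoed — aborts generation naming the conflict.

The headline configuration encodes the survey-scale community the
package's worked example reports: 516 sediment genomes, 132 in novel
families (97 names) and 208 in rare families (113 names); 149 sediment
genomes with at least one reductive/disproportionating capability (18
sulfate, 104 Asr, 8 Dsr-only, 20 Psr, 11 Phs, 73 Otr and 68 Ttr with 36
carrying both); 114 water genomes, 62 in sediment-shared families and 52
water-specific, 59 with at least one oxidative capability; sediment RED
values alternating 0.71/0.81 (mean 0.76); an Asr:Dsr TPM ratio of 4; and
an order/family structure that yields exactly 206 order-level plus 85
family-level lineage groups over the 630 genomes. Where the composition
is under-determined by those totals (which genomes overlap which
capabilities, family sizes within strata), one arrangement was fixed and
documented in the generator; overlaps were chosen so the capability
unions equal the stated totals exactly. Family labels are shuffled over
genome slots (seeded) so novelty strata and capabilities decorrelate.

What it does **not** emulate: sequences, assembly artifacts, chimeric
bins, annotation error structure (false-positive HMM hits above
threshold), inter-replicate TPM noise, or correlated taxonomy mistakes.
Passing tests therefore demonstrate that the decision layer is correct
and deterministic given its inputs — not that upstream annotation of real
data is reliable.

## Numerical and degenerate-input choices

* Percentages: half-up rounding (`round_half_up()`), never banker's.
* Completeness thresholds: exact rational comparison, inclusive.
* Empty inputs: empty hit tables give empty presence maps; an empty
  genome collection, an empty lineage group, or a RED-less collection
  raise explicit errors; a zero reference count in enrichment returns an
  undefined sentinel rather than dividing.
* Genomes above 10% contamination are rejected at load with their ids
  logged, mirroring bin-QC admission.
* Determinism: one seed drives every draw in the generator; integer
  plant logic plus seeded uniform draws make same-seed outputs
  byte-identical, and pipeline reruns on the same inputs are
  byte-identical (provenance comments carry no timestamps).

## Problem sizes

The packaged fixture is survey-scale (630 genomes, ~2.6k gene hits, ~17k
KO rows) and the whole suite — including 100 seeded replicates of the
rule-engine-versus-brute-force oracle on collections of up to 50 genomes
— completes in about a minute; property tests elsewhere use collections
of 5–60 genomes, sizes at which independent brute-force recounts stay
trivially cheap.

## Known limitations

* Novelty is only as good as the reference count table; synonymy between
  taxonomy releases is not resolved.
* Capability calls are genomic potential, not activity; expression
  aggregation is descriptive (no differential testing).
* The genus/species ranks are classified but excluded from headline
  summaries, which report novelty to family only.
* Multi-copy gene information is discarded by design; users needing copy
  number should work upstream of `gene_presence()`.
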