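# Default dissimilatory sulfur-cycling capability rules.
#
# Each rule names a capability, its direction (reduction /
# disproportionation / oxidation / flag), and a boolean requirement over
# canonical gene symbols using the combinators all / any /
# at_least {k, of} / not.  `exclude_taxa` vetoes a rule for genomes whose
# lineage contains any listed name at any rank (used to keep the
# reversible Dsr system out of lineages known to run it oxidatively).
# `exclude_capabilities` suppresses a call when a listed capability is
# active on the same genome (e.g. a full sulfate reducer is not also
# counted as a sulfite-only reducer).  `annotate` adds named evidence
# annotations when their expression is also satisfied.  The special node
# `context: other_oxidative` is true when the genome carries at least one
# other active oxidation-direction capability; it encodes "reversal of
# AprAB+QmoABC" being credible only in an otherwise oxidative genome.
version: 1
rules:
- name: sulfate_reduction
  direction: reduction
  require:
    all: [Sat, AprA, AprB, QmoA, QmoB, QmoC, DsrA, DsrB, DsrC]
- name: sulfite_reduction_dsr
  direction: reduction
  require:
    all:
    - all: [DsrA, DsrB, DsrC]
    - at_least: {k: 3, of: [DsrK, DsrM, DsrJ, DsrO, DsrP]}
  exclude_capabilities: [sulfate_reduction]
  exclude_taxa: [Proteobacteria, Nitrospirota, Nitrospira, Chlorobiaceae]
- name: sulfite_reduction_asr
  direction: reduction
  require:
    all: [AsrA, AsrB, AsrC]
  annotate:
    asr_hdr_locus:
      all: [HdrA, HdrB, HdrC]
- name: polysulfide_reduction
  direction: reduction
  require:
    all: [PsrA, PsrB, PsrC]
- name: sulfurhydrogenase
  direction: flag
  require:
    any:
    - all: [HydA, HydB, HydC, HydD]
    - all: [ShyA, ShyB, ShyC, ShyD]
- name: thiosulfate_reduction
  direction: reduction
  require:
    all:
    - all: [PhsA, PhsB, PhsC]
    - any:
      - all: [DsrA, DsrB, DsrC]
      - all: [AsrA, AsrB, AsrC]
- name: thiosulfate_disproportionation_phs
  direction: disproportionation
  require:
    all:
    - all: [PhsA, PhsB, PhsC]
    - any:
      - all: [AprA, AprB, Sat]
      - all: [SoeA, SoeB, SoeC]
      - SorA
- name: thiosulfate_disproportionation_rhd
  direction: disproportionation
  require:
    all:
    - Rhd
    - any:
      - all: [Sat, AprA, AprB]
      - all: [SoeA, SoeB, SoeC]
    - any:
      - all: [DsrA, DsrB, DsrC]
      - all: [AsrA, AsrB, AsrC]
- name: tetrathionate_reduction
  direction: reduction
  require:
    any:
    - Otr
    - all: [TtrA, TtrB, TtrC]
- name: sox_complete
  direction: oxidation
  require:
    all: [SoxA, SoxX, SoxB, SoxY, SoxZ, SoxC, SoxD]
- name: sulfide_oxidation
  direction: oxidation
  require:
    any:
    - all: [FccA, FccB]
    - Sqr
- name: sulfur_oxidation_rdsr
  direction: oxidation
  require:
    all:
    - all: [DsrA, DsrB, DsrC]
    - any:
      - all: [FccA, FccB]
      - Sqr
    - not:
        all: [Sat, AprA, AprB, QmoA, QmoB, QmoC]
- name: sulfite_oxidation
  direction: oxidation
  require:
    any:
    - all:
      - all: [AprA, AprB, QmoA, QmoB, QmoC, Sat]
      - context: other_oxidative
    - all: [SoeA, SoeB, SoeC]
    - all: [SorA, SorB]
- name: thiosulfate_oxidation_tetrathionate
  direction: oxidation
  require:
    any:
    - TsdA
    - all: [DoxA, DoxD]
- name: tetrathionate_hydrolysis
  direction: oxidation
  require:
    any: [TetH]
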