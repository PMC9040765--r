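# Illustrative default pathway definitions (synthetic KO numbers).
#
# KO-to-pathway lists are data that evolve with KEGG releases; this shipped
# file exists so the lineage-metabolism stage is runnable and testable out
# of the box.  Supply a curated file for real analyses.  `threshold` is the
# fraction of a pathway's KOs a single genome must carry (default 0.80).
pathways:
- name: hexose_degradation
  category: sugars
  kos: [K90001, K90002, K90003, K90004, K90005, K90006, K90007, K90008, K90009, K90010]
- name: pentose_degradation
  category: sugars
  kos: [K90011, K90012, K90013, K90014, K90015]
- name: amino_acid_catabolism
  category: amino acids
  kos: [K90021, K90022, K90023, K90024, K90025, K90026, K90027, K90028]
- name: scfa_oxidation
  category: SCFA
  kos: [K90031, K90032, K90033, K90034, K90035]
- name: lcfa_beta_oxidation
  category: LCFA beta-oxidation
  kos: [K90041, K90042, K90043, K90044, K90045, K90046]
- name: benzoate_degradation
  category: aromatics
  kos: [K90051, K90052, K90053, K90054, K90055, K90056, K90057]
- name: alkane_degradation
  category: alkanes
  kos: [K90061, K90062, K90063, K90064]
- name: wood_ljungdahl
  category: autotrophy
  kos: [K90071, K90072, K90073, K90074, K90075, K90076, K90077, K90078, K90079, K90080]
- name: hydrogenotrophy
  category: hydrogen oxidation
  kos: [K90081, K90082, K90083, K90084]
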