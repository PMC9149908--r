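Plain-text summaries of published extracellular-vesicle proteome surveys,
used as worked-example inputs and in the acceptance checks.

- `ev_survey_compartment_tallies.tsv` — per-compartment counts of proteins
  with organellar-map (hyperLOPIT u2os) coordinates for four detected sets:
  the MISEV2018 marker list, the Kowal et al. F3-100K benchmark exosome
  preparation, and the Kugeratski et al. core-exosome and all-cell-exosome
  sets.
- `ev_survey_identified_totals.tsv` — the total number of identified
  proteins in each of those sets (the mapped-fraction denominators).
- `ev_marker_recovery_f3_100k.tsv` — MISEV2018 category sizes and the
  number of each category detected in the Kowal et al. F3-100K benchmark
  preparation.
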