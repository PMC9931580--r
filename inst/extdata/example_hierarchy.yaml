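# Rank-priority order: earlier entries win ties in the majority vote.
lineages:
  Macrophage:
    - CD68
  Microglia:
    - P2Y12
  Endothelial:
    - CD31
  Astrocyte:
    - GFAP
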