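markers:
  - name: CD68
    role: lineage
    foreground_level: 5
    min_blob_area: 4
  - name: P2Y12
    role: lineage
    foreground_level: 5
    min_blob_area: 4
  - name: GFAP
    role: lineage
    foreground_level: 5
    min_blob_area: 6
    refine: yes
    sensitivity: 0.4
  - name: CD31
    role: lineage
    foreground_level: 4
    min_blob_area: 4
  - name: CD163
    role: functional
    foreground_level: 5
    min_blob_area: 4
  - name: MPO
    role: functional
    foreground_level: 5
    min_blob_area: 4
    enhance: yes
    low_pct: 1
    high_pct: 99
  - name: Ki67
    role: functional
    foreground_level: 5
    min_blob_area: 4
  - name: CC3
    role: functional
    foreground_level: 5
    min_blob_area: 4
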