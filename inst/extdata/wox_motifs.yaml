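# Peptide motif library for WOX superclade/clade classification.
#
# The three HD nonapeptide signatures and the two EAR variants are exact
# printed diagnostics. The WUS-box entry uses the literature consensus core
# (TL-x-LFP). Motifs marked `placeholder: true` stand in for clade motifs
# that are only depicted graphically in the source survey: their patterns
# are synthetic, editable stand-ins (the bundled simulator plants exactly
# these patterns, so synthetic-truth recovery is well defined).
version: 1
motifs:
  - name: HD-T1
    pattern: NVYNWFQNR
    label: T1
    region: HD-internal
    kind: superclade
  - name: HD-T2
    pattern: NVFYWFQNR
    label: T2
    region: HD-internal
    kind: superclade
  - name: HD-T3
    pattern: NVFYWFQNH
    label: T3
    region: HD-internal
    kind: superclade
  - name: WUS-box
    pattern: TL.LFP
    label: T3
    region: downstream-of-HD
    kind: superclade-support
  - name: EAR-WOX5/7
    pattern: L[DE]LRLS
    label: WOX5/7
    region: C-terminal
    kind: clade
  - name: EAR-WUS
    pattern: L[DE]L[ST]LN
    label: WUS
    region: C-terminal
    kind: clade
  - name: T1WOX-motif
    pattern: WSQNAHLPG
    label: WOX10/13/14
    region: upstream-of-HD
    kind: clade
    placeholder: true
  - name: T2WOX-motif
    pattern: VFINGQWPESLQ
    label: WOX8/9-11/12
    region: downstream-of-HD
    kind: clade
    placeholder: true
  - name: WOX2-motif
    pattern: CSNGESSTM
    label: WOX2
    region: C-terminal
    kind: clade
    placeholder: true
  - name: WOX1/6-motif
    pattern: GHLFDSIPR
    label: WOX1/6
    region: downstream-of-HD
    kind: clade
    placeholder: true
  - name: WOX4-motif
    pattern: APQHSWLRD
    label: WOX4
    region: upstream-of-HD
    kind: clade
    placeholder: true
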