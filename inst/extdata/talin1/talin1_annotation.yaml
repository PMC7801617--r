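# Talin-1 domain architecture and binding-site registry.
# Boundaries anchored on published construct/structure residue ranges for
# F2-F3, F3, R1, R3, R7 (discontinuous around R8), R9, R11, R13-DD and DD;
# gaps between anchors are closed by extending the earlier domain.
protein: TLN1
length: 2541
domains:
  - {name: F0, start: 1, end: 85}
  - {name: F1, start: 86, end: 207}
  - {name: F2, start: 208, end: 308}
  - {name: F3, start: 309, end: 405}
  - {name: linker, start: 406, end: 486}
  - {name: R1, start: 487, end: 656}
  - {name: R2, start: 657, end: 795}
  - {name: R3, start: 796, end: 909}
  - {name: R4, start: 910, end: 1044}
  - {name: R5, start: 1045, end: 1205}
  - {name: R6, start: 1206, end: 1351}
  - name: R7
    segments:
      - [1352, 1457]
      - [1585, 1659]
  - {name: R8, start: 1458, end: 1584}
  - {name: R9, start: 1660, end: 1822}
  - {name: R10, start: 1823, end: 1974}
  - {name: R11, start: 1975, end: 2140}
  - {name: R12, start: 2141, end: 2299}
  - {name: R13, start: 2300, end: 2493}
  - {name: DD, start: 2494, end: 2541}
binding_sites:
  # membrane-anchoring / integrin-activation helix of F3 (clamped to F3 end)
  - {name: integrin, host_domain: F3, intervals: [[385, 405]]}
  # DLC-1 LD-motif contacts in R8
  - {name: DLC-1, host_domain: R8, residues: [1530, 1544]}
  # approximate R9 surface patch at the autoinhibitory F3 interface
  - {name: autoinhibition, host_domain: R9, intervals: [[1761, 1772]]}
  # C-terminal actin-binding site; the DD part (dimerisation-dependent)
  - {name: ABS3, host_domain: DD, intervals: [[2494, 2541]]}
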