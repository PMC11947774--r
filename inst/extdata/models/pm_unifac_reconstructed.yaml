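name: P&M-UNIFAC
combinatorial: larsen_modified
T0: 298.15
provenance:
  - "RECONSTRUCTED (synthetic stand-in): the original sugar-group parameter
     tables were not available for verbatim transcription. This file encodes
     the variant's structure -- Larsen-modified combinatorial with dedicated
     sugar groups: a furanose ring group (FUR) and a ring hydroxyl (OHring)
     alongside the standard alkane and hydroxyl groups, with linearly
     temperature-dependent interactions -- using parameter values of
     representative magnitude. Its numerical predictions are illustrative,
     not the original model's."
subgroups:
  - {id: CH2,    main: CH2,    R: 0.6744, Q: 0.540}
  - {id: CH,     main: CH2,    R: 0.4469, Q: 0.228}
  - {id: OH,     main: OH,     R: 1.0000, Q: 1.200}
  - {id: OHring, main: OHring, R: 1.0000, Q: 1.200}
  - {id: FUR,    main: FUR,    R: 1.9000, Q: 1.500}
interactions:
  - {from: CH2,    to: OH,     a0: 900.0, a1: 0.25}
  - {from: OH,     to: CH2,    a0: 170.0, a1: -0.10}
  - {from: CH2,    to: OHring, a0: 820.0, a1: 0.20}
  - {from: OHring, to: CH2,    a0: 140.0, a1: -0.10}
  - {from: OH,     to: OHring, a0: 0.0,   a1: 0.0}
  - {from: OHring, to: OH,     a0: 0.0,   a1: 0.0}
  - {from: CH2,    to: FUR,    a0: 400.0, a1: 0.10}
  - {from: FUR,    to: CH2,    a0: 60.0,  a1: 0.0}
  - {from: OH,     to: FUR,    a0: 110.0, a1: 0.0}
  - {from: FUR,    to: OH,     a0: 150.0, a1: 0.0}
  - {from: OHring, to: FUR,    a0: 110.0, a1: 0.0}
  - {from: FUR,    to: OHring, a0: 150.0, a1: 0.0}
components:
  group_counts:
    fructose: {FUR: 1, CH2: 2, OHring: 5}
    glycerol: {CH2: 2, CH: 1, OH: 3}
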