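name: Bio-UNIFAC
combinatorial: larsen_modified
T0: 298.15
provenance:
  - "RECONSTRUCTED (synthetic stand-in): the original Bio-UNIFAC interaction
     tables were not available for verbatim transcription. This file encodes
     the variant's structure -- Larsen-modified combinatorial (r^(2/3) volume
     fractions) with linearly temperature-dependent interaction energies --
     using parameter values of representative magnitude. Its numerical
     predictions are illustrative, not the original model's."
subgroups:
  - {id: CH3,   main: CH2,   R: 0.9011, Q: 0.848}
  - {id: CH2,   main: CH2,   R: 0.6744, Q: 0.540}
  - {id: CH,    main: CH2,   R: 0.4469, Q: 0.228}
  - {id: OH,    main: OH,    R: 1.0000, Q: 1.200}
  - {id: CH2CO, main: CH2CO, R: 1.4457, Q: 1.180}
interactions:
  - {from: CH2,   to: OH,    a0: 900.0, a1: 0.25}
  - {from: OH,    to: CH2,   a0: 170.0, a1: -0.10}
  - {from: CH2,   to: CH2CO, a0: 500.0, a1: 0.10}
  - {from: CH2CO, to: CH2,   a0: 30.0,  a1: 0.0}
  - {from: OH,    to: CH2CO, a0: 90.0,  a1: 0.0}
  - {from: CH2CO, to: OH,    a0: 150.0, a1: 0.0}
components:
  group_counts:
    fructose: {CH2: 1, CH: 3, CH2CO: 1, OH: 5}
    glycerol: {CH2: 2, CH: 1, OH: 3}
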