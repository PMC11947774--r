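name: A-UNIFAC
combinatorial: staverman_guggenheim
T0: 298.15
provenance:
  - "RECONSTRUCTED (synthetic stand-in): the original A-UNIFAC parameter
     tables were not available for verbatim transcription. This file encodes
     the variant's structure -- Staverman-Guggenheim combinatorial, a
     Wertheim association contribution on hydroxyl sites with a dedicated
     ring-hydroxyl subgroup (OHring) for the sugar and a glycerol-specific
     hydroxyl (OHgly) -- with alkane/ketone residual parameters from the
     classical UNIFAC table and association parameters of representative
     hydroxyl magnitude. Its numerical predictions are illustrative, not the
     original model's."
subgroups:
  - {id: CH3,    main: CH2,    R: 0.9011, Q: 0.848}
  - {id: CH2,    main: CH2,    R: 0.6744, Q: 0.540}
  - {id: CH,     main: CH2,    R: 0.4469, Q: 0.228}
  - {id: OHring, main: OHring, R: 1.0000, Q: 1.200}
  - {id: OHgly,  main: OHgly,  R: 1.0000, Q: 1.200}
  - {id: CH2CO,  main: CH2CO,  R: 1.4457, Q: 1.180}
interactions:
  - {from: CH2,    to: OHring, a0: 986.5, a1: 0.0}
  - {from: OHring, to: CH2,    a0: 156.4, a1: 0.0}
  - {from: CH2,    to: OHgly,  a0: 986.5, a1: 0.0}
  - {from: OHgly,  to: CH2,    a0: 156.4, a1: 0.0}
  - {from: CH2,    to: CH2CO,  a0: 476.4, a1: 0.0}
  - {from: CH2CO,  to: CH2,    a0: 26.76, a1: 0.0}
  - {from: OHring, to: CH2CO,  a0: 84.00, a1: 0.0}
  - {from: CH2CO,  to: OHring, a0: 164.5, a1: 0.0}
  - {from: OHgly,  to: CH2CO,  a0: 84.00, a1: 0.0}
  - {from: CH2CO,  to: OHgly,  a0: 164.5, a1: 0.0}
  - {from: OHring, to: OHgly,  a0: 0.0,   a1: 0.0}
  - {from: OHgly,  to: OHring, a0: 0.0,   a1: 0.0}
association:
  - {subgroup: OHring, donors: 1, acceptors: 1, eps_over_k: 2700.0, kappa: 0.008}
  - {subgroup: OHgly,  donors: 1, acceptors: 1, eps_over_k: 2700.0, kappa: 0.008}
components:
  group_counts:
    fructose: {CH2: 1, CH: 3, CH2CO: 1, OHring: 5}
    glycerol: {CH2: 2, CH: 1, OHgly: 3}
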