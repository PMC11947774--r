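name: UNIFAC
combinatorial: staverman_guggenheim
T0: 298.15
provenance:
  - "Classical published UNIFAC (VLE) volume/area parameters R_k, Q_k for the
     alkane (CH3/CH2/CH), hydroxyl (OH) and ketone (CH3CO/CH2CO) subgroups and
     the corresponding main-group interaction energies (temperature
     independent, a1 = 0)."
  - "Open-chain ketose decomposition of fructose (1 CH2CO, 1 CH2, 3 CH, 5 OH);
     glycerol as 2 CH2, 1 CH, 3 OH."
subgroups:
  - {id: CH3,   main: CH2,   R: 0.9011, Q: 0.848}
  - {id: CH2,   main: CH2,   R: 0.6744, Q: 0.540}
  - {id: CH,    main: CH2,   R: 0.4469, Q: 0.228}
  - {id: OH,    main: OH,    R: 1.0000, Q: 1.200}
  - {id: CH3CO, main: CH2CO, R: 1.6724, Q: 1.488}
  - {id: CH2CO, main: CH2CO, R: 1.4457, Q: 1.180}
interactions:
  - {from: CH2,   to: OH,    a0: 986.5,  a1: 0.0}
  - {from: OH,    to: CH2,   a0: 156.4,  a1: 0.0}
  - {from: CH2,   to: CH2CO, a0: 476.4,  a1: 0.0}
  - {from: CH2CO, to: CH2,   a0: 26.76,  a1: 0.0}
  - {from: OH,    to: CH2CO, a0: 84.00,  a1: 0.0}
  - {from: CH2CO, to: OH,    a0: 164.5,  a1: 0.0}
components:
  group_counts:
    fructose: {CH2: 1, CH: 3, CH2CO: 1, OH: 5}
    glycerol: {CH2: 2, CH: 1, OH: 3}
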