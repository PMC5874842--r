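# Eudragit L100: methacrylic acid / methyl methacrylate copolymer, 1:1.
name: Eudragit L100
abbreviation: EUD
role: polymer
mw: 125000
density: 1.28
tg_c: 192
repeat_units:
  - name: methacrylic acid
    fraction: 0.5
    groups:
      fedors: {CH2: 1, C: 1, CH3: 1, COOH: 1}
      van_krevelen: {CH2: 1, C: 1, CH3: 1, COOH: 1}
  - name: methyl methacrylate
    fraction: 0.5
    groups:
      fedors: {CH2: 1, C: 1, CH3: 2, COO: 1}
      van_krevelen: {CH2: 1, C: 1, CH3: 2, COO: 1}
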