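# Eudragit L100-55: methacrylic acid / ethyl acrylate copolymer, 1:1.
name: Eudragit L100-55
abbreviation: EUD55
role: polymer
mw: 320000
density: 1.25
tg_c: 122
repeat_units:
  - name: methacrylic acid
    fraction: 0.5
    groups:
      fedors: {CH2: 1, C: 1, CH3: 1, COOH: 1}
      van_krevelen: {CH2: 1, C: 1, CH3: 1, COOH: 1}
  - name: ethyl acrylate
    fraction: 0.5
    groups:
      fedors: {CH2: 2, CH: 1, COO: 1, CH3: 1}
      van_krevelen: {CH2: 2, CH: 1, COO: 1, CH3: 1}
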