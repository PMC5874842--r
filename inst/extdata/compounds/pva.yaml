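# PVPVA: vinylpyrrolidone / vinyl acetate copolymer, mole ratio 0.6:0.4.
name: PVPVA copolymer
abbreviation: PVA
role: polymer
mw: 57500
density: 1.27
tg_c: 112
repeat_units:
  - name: vinylpyrrolidone
    fraction: 0.6
    groups:
      fedors: {CH2: 4, CH: 1, CON: 1, ring_ge5: 1}
      van_krevelen: {CH2: 4, CH: 1, CO: 1, "N": 1, ring_ge5: 1}
  - name: vinyl acetate
    fraction: 0.4
    groups:
      fedors: {CH2: 1, CH: 1, COO: 1, CH3: 1}
      van_krevelen: {CH2: 1, CH: 1, COO: 1, CH3: 1}
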