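# Soluplus: polyvinyl caprolactam / polyvinyl acetate / polyethylene glycol
# graft copolymer, repeat-unit mole fractions 0.57:0.30:0.13.
name: Soluplus
abbreviation: SOL
role: polymer
mw: 115000
density: 1.03
tg_c: 80
repeat_units:
  - name: vinylcaprolactam
    fraction: 0.57
    groups:
      fedors: {CH2: 6, CH: 1, CON: 1, ring_ge5: 1}
      van_krevelen: {CH2: 6, CH: 1, CO: 1, "N": 1, ring_ge5: 1}
  - name: vinyl acetate
    fraction: 0.30
    groups:
      fedors: {CH2: 1, CH: 1, COO: 1, CH3: 1}
      van_krevelen: {CH2: 1, CH: 1, COO: 1, CH3: 1}
  - name: ethylene glycol
    fraction: 0.13
    groups:
      fedors: {CH2: 2, O: 1}
      van_krevelen: {CH2: 2, O: 1}
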