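# Polyvinylpyrrolidone K30. Repeat unit: vinylpyrrolidone.
# Fedors: lactam as the combined tertiary-amide increment CON.
# Van Krevelen: no combined amide entry; split into CO + N (hence the
# larger van Krevelen repeat-unit volume).
name: Polyvinylpyrrolidone K30
abbreviation: PK30
role: polymer
mw: 50000
density: 1.18
tg_c: 162
groups:
  fedors: {CH2: 4, CH: 1, CON: 1, ring_ge5: 1}
  van_krevelen: {CH2: 4, CH: 1, CO: 1, "N": 1, ring_ge5: 1}
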