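# Ibuprofen: 2-(4-isobutylphenyl)propanoic acid.
# Fragmentation: 3x CH3, 2x CH (benzylic / isobutyl branch), 1x CH2,
# para-disubstituted benzene ring, carboxylic acid.
name: Ibuprofen
abbreviation: IBU
role: drug
mw: 206
tg_c: -44
tm_c: 76
gfa_class: III
groups:
  fedors: {CH3: 3, CH: 2, CH2: 1, phenylene: 1, COOH: 1}
  van_krevelen: {CH3: 3, CH: 2, CH2: 1, phenylene: 1, COOH: 1}
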