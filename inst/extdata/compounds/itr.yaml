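# Itraconazole: triazole antifungal, C35H38Cl2N8O4.
# Large multi-ring molecule: dichlorophenyl (trisubstituted ring), dioxolane,
# 1,2,4-triazole, two para-phenylene rings, piperazine, triazolone, sec-butyl.
# Fedors: azole rings carry azomethine (N=), ring-closure and conjugated
# double-bond corrections; the triazolone carbonyl is taken as ketone CO with
# ring nitrogens counted separately. Van Krevelen: no conjugation or
# azomethine increments exist, so ring nitrogens are counted as tertiary N,
# all four non-benzenoid rings as plain ring closures, and the trisubstituted
# dichlorophenyl volume as the disubstituted aromatic increment (the data set
# has no trisubstituted volume entry); this fragmentation difference produces
# the larger van Krevelen molar volume.
name: Itraconazole
abbreviation: ITR
role: drug
mw: 705
tg_c: 59
tm_c: 168
gfa_class: III
groups:
  fedors: {CH3: 2, CH2: 8, CH: 2, C: 1, O: 3, phenylene: 2, phenyl_3sub: 1, Cl: 2, =CH-: 3, N=: 2, "N": 6, CO: 1, ring_ge5: 3, conj_db: 11}
  van_krevelen: {CH3: 2, CH2: 8, CH: 2, C: 1, O: 3, phenylene: 3, Cl: 2, =CH-: 3, "N": 8, CO: 1, ring_ge5: 4}
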