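# Naproxen: 2-(6-methoxynaphthalen-2-yl)propanoic acid.
# The fused naphthalene core has no dedicated increment in either data set.
# Fedors: one aromatic ring as phenylene plus the second ring built from
# unsaturated CH/C increments with ring-closure and conjugated-double-bond
# corrections. Van Krevelen lacks those corrections, so the core is
# approximated as two fused phenylene units (hence the larger molar volume).
name: Naproxen
abbreviation: NAP
role: drug
mw: 230
tg_c: 6
tm_c: 158
gfa_class: I
groups:
  fedors: {CH3: 2, CH: 1, COOH: 1, O: 1, phenylene: 1, =CH-: 2, =C<: 2, ring_ge5: 1, conj_db: 2}
  van_krevelen: {CH3: 2, CH: 1, COOH: 1, O: 1, phenylene: 2}
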