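# Carbamazepine: 5H-dibenzo[b,f]azepine-5-carboxamide.
# Two ortho-fused benzene rings as phenylene, the azepine CH=CH bridge as
# unsaturated CH increments, ring closure for the seven-membered ring.
# Fedors provides a primary-amide increment (CONH2); the van Krevelen set
# does not, so there the amide is split into CO + NH2.
name: Carbamazepine
abbreviation: CAR
role: drug
mw: 236
tg_c: 50
tm_c: 177
gfa_class: I
groups:
  fedors: {phenylene: 2, =CH-: 2, "N": 1, CONH2: 1, ring_ge5: 1, conj_db: 1}
  van_krevelen: {phenylene: 2, =CH-: 2, "N": 1, CO: 1, NH2: 1, ring_ge5: 1}
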