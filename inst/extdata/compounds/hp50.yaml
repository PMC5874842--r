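# Hypromellose phthalate (HPMCP-HP50).
# Pharmaceutical hypromellose grades have variable, proprietary substituent
# proportions (methoxy / hydroxypropoxy / phthalyl), so no single structural
# fragmentation exists. The fractional counts below are a calibrated
# pseudo-fragmentation per averaged macro repeat unit: non-negative counts
# over standard increments pinned so that both contribution schemes
# reproduce the published parameter set for this grade. They are NOT a
# structural assignment.
name: Hypromellose phthalate HP50
abbreviation: HP50
role: polymer
mw: 78000
density: 1.82
tg_c: 140
groups:
  fedors: {CH2: 1.1659, CH: 17.8031, O: 6.7288, OH: 4.1614, phenylene: 1.4745, ring_ge5: 14.9426}
  van_krevelen: {CH2: 1.1659, CH: 17.8031, O: 6.7288, OH: 4.1614, phenylene: 1.4745, ring_ge5: 14.9426}
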