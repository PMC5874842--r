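# Hypromellose acetate succinate, fine grade (HPMCAS-LF).
# As for HP50, substituent proportions vary by grade; the fractional counts
# are a calibrated pseudo-fragmentation per averaged macro repeat unit
# reproducing the published parameter set, not a structural assignment.
name: Hypromellose acetate succinate LF
abbreviation: HAS
role: polymer
mw: 18167
density: 1.29
tg_c: 122
groups:
  fedors: {CH2: 0.4038, CH: 19.4402, O: 7.5138, OH: 3.9688, ring_ge5: 18.0750}
  van_krevelen: {CH2: 0.4038, CH: 19.4402, O: 7.5138, OH: 3.9688, ring_ge5: 18.0750}
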