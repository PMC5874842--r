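# Published top-3 polymer rankings per predictive method and drug, with the
# printed position-match (f1) and identity-match (f2) concordance scores
# against the spray-dryer reference. Polymer abbreviations normalized.
# Methods: delta_chi_f / delta_chi_vk (Greenhalgh + Flory-Huggins rankings,
# identical order per scheme), euc_d (Bagley distance), fc_rt / fc_rp (film
# casting at room temperature / reduced pressure), qc (quench cooling),
# ad (atomization device), sd (spray dryer reference).
method	drug	rank1	rank2	rank3	f1	f2
delta_chi_f	IBU	EUD	SOL	EUD55	0	0.33
delta_chi_f	NAP	EUD55	SOL	EUD	0.33	0.33
delta_chi_f	CAR	PK30	HP50	HAS	0	0.33
delta_chi_f	ITR	HP50	HAS	PK30	0	0.33
delta_chi_vk	IBU	EUD55	EUD	SOL	0.33	0.33
delta_chi_vk	NAP	EUD55	EUD	SOL	0	0.33
delta_chi_vk	CAR	PVA	HAS	PK30	0	0.33
delta_chi_vk	ITR	HAS	PK30	HP50	0.33	0.33
euc_d	IBU	SOL	EUD55	EUD	0	0.33
euc_d	NAP	SOL	PVA	EUD	0.66	0.66
euc_d	CAR	PVA	PK30	SOL	0.33	0.33
euc_d	ITR	PVA	PK30	SOL	0	0
fc_rt	IBU	PK30	PVA	SOL	1	1
fc_rt	NAP	SOL	PK30	HAS	0	0.33
fc_rt	CAR	EUD	PK30	HAS	0.66	0.66
fc_rt	ITR	EUD	EUD55	HP50	1	1
fc_rp	IBU	PVA	PK30	SOL	0.33	1
fc_rp	NAP	SOL	PVA	PK30	0.33	0.66
fc_rp	CAR	PK30	EUD	HAS	0	0.66
fc_rp	ITR	HAS	HP50	EUD55	0	0.66
qc	IBU	PK30	PVA	HAS	0.66	0.66
qc	NAP	PK30	PVA	SOL	0.66	0.66
qc	CAR	PK30	PVA	SOL	0	0.33
qc	ITR	EUD	EUD55	HAS	0.66	0.66
ad	IBU	PK30	PVA	SOL	1	1
ad	NAP	PK30	PVA	SOL	0.66	0.66
ad	CAR	EUD	PK30	EUD55	1	1
ad	ITR	EUD	EUD55	HP50	1	1
sd	IBU	PK30	PVA	SOL	NA	NA
sd	NAP	PK30	PVA	EUD	NA	NA
sd	CAR	EUD	PK30	EUD55	NA	NA
sd	ITR	EUD	EUD55	HP50	NA	NA
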