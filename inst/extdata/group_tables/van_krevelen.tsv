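# Hoftyzer-van Krevelen group contributions for the dispersive (Fd),
# polar (Fp) and hydrogen-bonding (Eh) components.
# Fd, Fp: (J cm^3)^(1/2)/mol; Eh: J/mol; V: molar volume (cm^3/mol),
# taken from the Fedors volume increments for the same labels (the
# van Krevelen data set does not provide its own volume column).
# neg_v as in fedors.tsv. Fd may be negative for branch carbons.
label	Fd	Fp	Eh	V	neg_v
CH3	420	0	0	33.5	FALSE
CH2	270	0	0	16.1	FALSE
CH	80	0	0	-1.0	TRUE
C	-70	0	0	-19.2	TRUE
CH2=	400	0	0	28.5	FALSE
=CH-	200	0	0	13.5	FALSE
=C<	70	0	0	-5.5	TRUE
phenyl	1430	110	0	71.4	FALSE
phenylene	1270	110	0	52.4	FALSE
phenyl_3sub	1110	110	0	33.4	FALSE
ring_ge5	190	0	0	16.0	FALSE
ring_3_4	190	0	0	18.0	FALSE
COOH	530	420	10000	28.5	FALSE
COO	390	490	7000	18.0	FALSE
CO	290	770	2000	10.8	FALSE
O	100	400	3000	3.8	FALSE
OH	210	500	20000	10.0	FALSE
NH2	280	0	8400	19.2	FALSE
NH	160	210	3100	4.5	FALSE
N	20	800	5000	-9.0	TRUE
CN	430	1100	2500	24.0	FALSE
Cl	450	550	400	24.0	FALSE
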