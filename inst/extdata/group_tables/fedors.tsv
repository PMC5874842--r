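# Fedors cohesive-energy / molar-volume group contributions.
# E: cohesive energy (J/mol); V: molar volume (cm^3/mol).
# neg_v marks branching / ring-junction / correction entries whose volume
# increment is legitimately negative.
label	E	V	neg_v
CH3	4710	33.5	FALSE
CH2	4940	16.1	FALSE
CH	3430	-1.0	TRUE
C	1470	-19.2	TRUE
CH2=	4310	28.5	FALSE
=CH-	4310	13.5	FALSE
=C<	4310	-5.5	TRUE
phenyl	31940	71.4	FALSE
phenylene	31940	52.4	FALSE
phenyl_3sub	31940	33.4	FALSE
phenyl_4sub	31940	14.4	FALSE
ring_ge5	1050	16.0	FALSE
ring_3_4	3140	18.0	FALSE
conj_db	1670	-2.2	TRUE
COOH	27630	28.5	FALSE
COO	18000	18.0	FALSE
CO	17370	10.8	FALSE
O	3350	3.8	FALSE
OH	29800	10.0	FALSE
NH2	12560	19.2	FALSE
NH	8370	4.5	FALSE
N	4190	-9.0	TRUE
N=	11720	5.0	FALSE
CONH2	41860	17.5	FALSE
CONH	33490	9.5	FALSE
CON	29260	-7.7	TRUE
CN	25530	24.0	FALSE
Cl	11550	24.0	FALSE
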