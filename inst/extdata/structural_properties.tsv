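# Dinucleotide structural profile property table: 12 properties x 16 dinucleotides.
# Columns are the dinucleotides in lexicographic order AA..TT; one property per row.
# Values are a representative compilation from the primary dinucleotide-property
# literature and satisfy reverse-complement symmetry:
#   SP1  A-philicity            (Ivanov & Minchenkova 1995; representative surrogate values)
#   SP2  base stacking energy   (Ornstein et al. 1978, kcal/mol)
#   SP3  B-DNA twist            (Gorin et al. 1995, degrees)
#   SP4  bendability            (Brukner et al. 1995, DNase I-derived)
#   SP5  bending stiffness      (Sivolob & Khrapunov 1995)
#   SP6  DNA denaturation       (Blake & Delcourt 1998 / Gotoh & Tagashira scale)
#   SP7  duplex disrupt energy  (Breslauer et al. 1986, kcal/mol)
#   SP8  duplex free energy     (SantaLucia et al. 1996, kcal/mol)
#   SP9  propeller twist        (el Hassan & Calladine 1996, degrees)
#   SP10 protein deformation    (Olson et al. 1998)
#   SP11 protein-DNA twist      (Olson et al. 1998, degrees)
#   SP12 Z-DNA forming energy   (Ho et al. 1986, kcal/mol)
# Published tabulations vary slightly between compilations; a user-supplied table in
# the same format may be substituted everywhere this file is consumed.
property	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT
A-philicity	-0.20	0.75	0.45	-0.58	0.18	1.10	1.27	0.45	0.60	1.44	1.10	0.75	-0.73	0.60	0.18	-0.20
base_stacking	-5.37	-10.51	-6.78	-6.57	-6.57	-8.26	-9.69	-6.78	-9.81	-14.59	-8.26	-10.51	-3.82	-9.81	-6.57	-5.37
b_dna_twist	35.62	34.40	27.70	31.50	34.50	33.67	29.80	27.70	36.90	40.00	33.67	34.40	36.00	36.90	34.50	35.62
bendability	-0.274	-0.205	-0.081	-0.280	0.017	-0.032	-0.280	-0.081	0.027	0.076	-0.032	-0.205	0.182	0.027	0.017	-0.274
bending_stiffness	35	60	60	20	60	130	85	60	60	85	130	60	20	60	60	35
dna_denaturation	54.50	97.73	58.42	57.02	54.71	85.97	72.55	58.42	86.44	136.12	85.97	97.73	36.73	86.44	54.71	54.50
duplex_disrupt_energy	1.9	1.3	1.6	1.5	1.9	3.1	3.6	1.6	1.6	3.1	3.1	1.3	0.9	1.6	1.9	1.9
duplex_free_energy	-1.00	-1.44	-1.28	-0.88	-1.45	-1.84	-2.17	-1.28	-1.30	-2.24	-1.84	-1.44	-0.58	-1.30	-1.45	-1.00
propeller_twist	-18.66	-13.10	-14.00	-15.01	-9.45	-8.11	-10.03	-14.00	-13.48	-11.08	-8.11	-13.10	-11.85	-13.48	-9.45	-18.66
protein_deformation	2.9	2.3	2.1	1.6	9.8	6.1	12.1	2.1	4.5	4.0	6.1	2.3	6.3	4.5	9.8	2.9
protein_dna_twist	35.1	31.5	31.9	29.3	37.3	32.9	36.1	31.9	36.3	33.6	32.9	31.5	37.8	36.3	37.3	35.1
z_dna	3.9	4.6	3.4	5.9	1.3	2.4	0.7	3.4	3.4	4.0	2.4	4.6	2.5	3.4	1.3	3.9
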