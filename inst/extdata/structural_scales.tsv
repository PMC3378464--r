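feature	kmer	value
Propeller twist	AA	-18.66
Propeller twist	AC	-13.1
Propeller twist	AG	-14
Propeller twist	AT	-15.01
Propeller twist	CA	-9.45
Propeller twist	CC	-8.11
Propeller twist	CG	-10.03
Propeller twist	CT	-14
Propeller twist	GA	-13.48
Propeller twist	GC	-11.08
Propeller twist	GG	-8.11
Propeller twist	GT	-13.1
Propeller twist	TA	-11.85
Propeller twist	TC	-13.48
Propeller twist	TG	-9.45
Propeller twist	TT	-18.66
DNA denaturation	AA	54.5
DNA denaturation	AC	97.73
DNA denaturation	AG	58.42
DNA denaturation	AT	57.02
DNA denaturation	CA	54.71
DNA denaturation	CC	85.97
DNA denaturation	CG	72.55
DNA denaturation	CT	58.42
DNA denaturation	GA	86.44
DNA denaturation	GC	136.12
DNA denaturation	GG	85.97
DNA denaturation	GT	97.73
DNA denaturation	TA	36.73
DNA denaturation	TC	86.44
DNA denaturation	TG	54.71
DNA denaturation	TT	54.5
DNA-bending stiffness	AA	35
DNA-bending stiffness	AC	60
DNA-bending stiffness	AG	60
DNA-bending stiffness	AT	20
DNA-bending stiffness	CA	60
DNA-bending stiffness	CC	130
DNA-bending stiffness	CG	85
DNA-bending stiffness	CT	60
DNA-bending stiffness	GA	60
DNA-bending stiffness	GC	85
DNA-bending stiffness	GG	130
DNA-bending stiffness	GT	60
DNA-bending stiffness	TA	20
DNA-bending stiffness	TC	60
DNA-bending stiffness	TG	60
DNA-bending stiffness	TT	35
Bendability	AAA	-0.274
Bendability	AAC	-0.205
Bendability	AAG	-0.081
Bendability	AAT	-0.28
Bendability	ACA	-0.006
Bendability	ACC	-0.032
Bendability	ACG	-0.033
Bendability	ACT	-0.183
Bendability	AGA	0.027
Bendability	AGC	0.017
Bendability	AGG	-0.057
Bendability	AGT	-0.183
Bendability	ATA	0.182
Bendability	ATC	-0.11
Bendability	ATG	0.134
Bendability	ATT	-0.28
Bendability	CAA	0.015
Bendability	CAC	0.04
Bendability	CAG	0.175
Bendability	CAT	0.134
Bendability	CCA	-0.246
Bendability	CCC	-0.012
Bendability	CCG	-0.136
Bendability	CCT	-0.057
Bendability	CGA	-0.003
Bendability	CGC	-0.077
Bendability	CGG	-0.136
Bendability	CGT	-0.033
Bendability	CTA	0.09
Bendability	CTC	-0.045
Bendability	CTG	0.175
Bendability	CTT	-0.081
Bendability	GAA	-0.037
Bendability	GAC	-0.013
Bendability	GAG	-0.045
Bendability	GAT	-0.11
Bendability	GCA	0.076
Bendability	GCC	0.107
Bendability	GCG	-0.077
Bendability	GCT	0.017
Bendability	GGA	0.013
Bendability	GGC	0.107
Bendability	GGG	-0.012
Bendability	GGT	-0.032
Bendability	GTA	0.025
Bendability	GTC	-0.013
Bendability	GTG	0.04
Bendability	GTT	-0.205
Bendability	TAA	0.068
Bendability	TAC	0.025
Bendability	TAG	0.09
Bendability	TAT	0.182
Bendability	TCA	0.194
Bendability	TCC	0.013
Bendability	TCG	-0.003
Bendability	TCT	0.027
Bendability	TGA	0.194
Bendability	TGC	0.076
Bendability	TGG	-0.246
Bendability	TGT	-0.006
Bendability	TTA	0.068
Bendability	TTC	-0.037
Bendability	TTG	0.015
Bendability	TTT	-0.274
Duplex disrupt energy	AA	9.1
Duplex disrupt energy	AC	6.5
Duplex disrupt energy	AG	7.8
Duplex disrupt energy	AT	8.6
Duplex disrupt energy	CA	5.8
Duplex disrupt energy	CC	11
Duplex disrupt energy	CG	11.9
Duplex disrupt energy	CT	7.8
Duplex disrupt energy	GA	5.6
Duplex disrupt energy	GC	11.1
Duplex disrupt energy	GG	11
Duplex disrupt energy	GT	6.5
Duplex disrupt energy	TA	6
Duplex disrupt energy	TC	5.6
Duplex disrupt energy	TG	5.8
Duplex disrupt energy	TT	9.1
Stacking energy	AA	-5.37
Stacking energy	AC	-10.51
Stacking energy	AG	-6.78
Stacking energy	AT	-6.57
Stacking energy	CA	-6.57
Stacking energy	CC	-8.26
Stacking energy	CG	-9.69
Stacking energy	CT	-6.78
Stacking energy	GA	-9.81
Stacking energy	GC	-14.59
Stacking energy	GG	-8.26
Stacking energy	GT	-10.51
Stacking energy	TA	-3.82
Stacking energy	TC	-9.81
Stacking energy	TG	-6.57
Stacking energy	TT	-5.37
Z-DNA	AA	3.9
Z-DNA	AC	4.6
Z-DNA	AG	3.4
Z-DNA	AT	5.9
Z-DNA	CA	1.3
Z-DNA	CC	2.4
Z-DNA	CG	0.7
Z-DNA	CT	3.4
Z-DNA	GA	3.4
Z-DNA	GC	4
Z-DNA	GG	2.4
Z-DNA	GT	4.6
Z-DNA	TA	2.5
Z-DNA	TC	3.4
Z-DNA	TG	1.3
Z-DNA	TT	3.9
Duplex free energy	AA	-1.9
Duplex free energy	AC	-1.3
Duplex free energy	AG	-1.6
Duplex free energy	AT	-1.5
Duplex free energy	CA	-1.9
Duplex free energy	CC	-3.1
Duplex free energy	CG	-3.6
Duplex free energy	CT	-1.6
Duplex free energy	GA	-1.6
Duplex free energy	GC	-3.1
Duplex free energy	GG	-3.1
Duplex free energy	GT	-1.3
Duplex free energy	TA	-0.9
Duplex free energy	TC	-1.6
Duplex free energy	TG	-1.9
Duplex free energy	TT	-1.9
Aphilicity	AA	-0.06
Aphilicity	AC	1.5
Aphilicity	AG	0.68
Aphilicity	AT	1.07
Aphilicity	CA	0.93
Aphilicity	CC	1.16
Aphilicity	CG	1.99
Aphilicity	CT	0.68
Aphilicity	GA	0.13
Aphilicity	GC	1.25
Aphilicity	GG	1.16
Aphilicity	GT	1.5
Aphilicity	TA	-1.38
Aphilicity	TC	0.13
Aphilicity	TG	0.93
Aphilicity	TT	-0.06
Protein-DNA twist	AA	35.1
Protein-DNA twist	AC	31.5
Protein-DNA twist	AG	31.9
Protein-DNA twist	AT	29.3
Protein-DNA twist	CA	37.3
Protein-DNA twist	CC	32.9
Protein-DNA twist	CG	36.1
Protein-DNA twist	CT	31.9
Protein-DNA twist	GA	36.3
Protein-DNA twist	GC	33.6
Protein-DNA twist	GG	32.9
Protein-DNA twist	GT	31.5
Protein-DNA twist	TA	37.8
Protein-DNA twist	TC	36.3
Protein-DNA twist	TG	37.3
Protein-DNA twist	TT	35.1
B-DNA twist	AA	35.62
B-DNA twist	AC	34.4
B-DNA twist	AG	27.7
B-DNA twist	AT	31.5
B-DNA twist	CA	34.5
B-DNA twist	CC	33.67
B-DNA twist	CG	29.8
B-DNA twist	CT	27.7
B-DNA twist	GA	36.9
B-DNA twist	GC	40
B-DNA twist	GG	33.67
B-DNA twist	GT	34.4
B-DNA twist	TA	36
B-DNA twist	TC	36.9
B-DNA twist	TG	34.5
B-DNA twist	TT	35.62
Protein deformation	AA	2.9
Protein deformation	AC	2.3
Protein deformation	AG	2.1
Protein deformation	AT	1.6
Protein deformation	CA	9.8
Protein deformation	CC	6.1
Protein deformation	CG	12.1
Protein deformation	CT	2.1
Protein deformation	GA	4.5
Protein deformation	GC	4
Protein deformation	GG	6.1
Protein deformation	GT	2.3
Protein deformation	TA	6.3
Protein deformation	TC	4.5
Protein deformation	TG	9.8
Protein deformation	TT	2.9
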