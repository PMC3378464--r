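feature	k	sign_class	units
Propeller twist	2	positive	degrees
DNA denaturation	2	positive	degrees Celsius
DNA-bending stiffness	2	positive	relative force constant
Bendability	3	positive	DNase I cutting propensity
Duplex disrupt energy	2	positive	kcal/mol
Stacking energy	2	negative	kcal/mol
Z-DNA	2	negative	kcal/mol
Duplex free energy	2	negative	kcal/mol
Aphilicity	2	negative	free energy (relative)
Protein-DNA twist	2	negative	degrees
B-DNA twist	2	negative	degrees
Protein deformation	2	negative	dimensionless
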