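segment	from	to	prob
core	A	A	0.016288
core	A	C	0.014166
core	A	G	0.956401
core	A	T	0.013144
core	C	A	0.005008
core	C	C	0.473094
core	C	G	0.150619
core	C	T	0.371278
core	G	A	0.024791
core	G	C	0.783690
core	G	G	0.184163
core	G	T	0.007357
core	T	A	0.791014
core	T	C	0.005436
core	T	G	0.029218
core	T	T	0.174332
linker	A	A	0.293594
linker	A	C	0.337581
linker	A	G	0.005000
linker	A	T	0.363824
linker	C	A	0.945780
linker	C	C	0.010013
linker	C	G	0.031449
linker	C	T	0.012758
linker	G	A	0.220453
linker	G	C	0.006974
linker	G	G	0.029676
linker	G	T	0.742897
linker	T	A	0.005614
linker	T	C	0.816925
linker	T	G	0.151988
linker	T	T	0.025473
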