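SNP	A1	WEIGHT	SOURCE
rs6656401	A	0.155	synthetic
rs6733839	T	0.202	synthetic
rs10933431	G	-0.080	synthetic
rs9271058	A	0.098	synthetic
rs75932628	T	0.470	synthetic
rs9473117	C	0.077	synthetic
rs12539172	T	-0.077	synthetic
rs10808026	A	-0.073	synthetic
rs73223431	T	0.077	synthetic
rs9331896	C	-0.128	synthetic
rs3740688	G	-0.072	synthetic
rs983392	G	-0.086	synthetic
rs10792832	A	-0.116	synthetic
rs11218343	C	-0.199	synthetic
rs17125924	G	0.131	synthetic
rs12881735	C	-0.062	synthetic
rs4147929	A	0.131	synthetic
rs3865444	A	-0.061	synthetic
rs6024870	A	-0.077	synthetic
rs7274581	C	-0.086	synthetic
rs190982	G	-0.058	synthetic
rs10498633	T	-0.091	synthetic
rs35349669	T	0.076	synthetic
rs1476679	C	-0.074	synthetic
rs10838725	C	0.077	synthetic
rs28834970	C	0.096	synthetic
rs11771145	A	-0.077	synthetic
rs2718058	G	-0.065	synthetic
rs59735493	A	-0.058	synthetic
rs113260531	A	0.095	synthetic
rs6014724	G	-0.106	synthetic
rs7920721	G	0.067	synthetic
rs138190086	A	0.131	synthetic
rs616338	T	0.300	synthetic
rs442495	C	-0.063	synthetic
rs117618017	T	0.095	synthetic
rs7185636	C	-0.070	synthetic
rs62039712	A	0.159	synthetic
rs2830500	A	-0.057	synthetic
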