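class	dfg	alpha_c	a_loop	pockets	hotspots	interactions	features
I	in	in	in	AP,SP	2,3	H-bond	HD1,HA2,HD2,HD3,Ar1
I1/2	in	in	in	BP,AP,RP,PP	1,2,6	H-bond	HA1,HD1,HA2,HD2,Ar1,L,HD4,HA3
II	out,out_up	out	out	AP,RP,PP,HPII	2,3,4,5,6,7	H-bond,cation-pi,pi-pi,CH-pi	HD1,HA2,HD2,Ar1,L,HD4,HA3,Ar2
III	out,out_up	out	out	PP,HPII	5,6,7	H-bond,cation-pi,pi-pi,CH-pi	HD4,HA3,Ar2
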