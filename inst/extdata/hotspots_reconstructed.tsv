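hotspot	pocket	bits	interactions	features
1	BP	1	H-bond	HD
2	AP	2,3,4,5	H-bond	HD,HA
3	AP	14	pi-pi,CH-pi	Ar
4	RP	11	pi-pi,H-bond	Ar,HD
5	PP	7,10	H-bond,cation-pi,salt-bridge	HD,Ar
6	HPII	6,8	H-bond	HD
7	HPII	9,12,13	pi-pi,H-bond	Ar,HA
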