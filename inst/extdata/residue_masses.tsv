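letter	mass	name
G	57.02146	Gly
A	71.03711	Ala
S	87.03203	Ser
P	97.05276	Pro
V	99.06841	Val
T	101.04768	Thr
C	103.00919	Cys
L	113.08406	Leu
I	113.08406	Ile
N	114.04293	Asn
D	115.02694	Asp
Q	128.05858	Gln
K	128.09496	Lys
E	129.04259	Glu
M	131.04049	Met
H	137.05891	His
F	147.06841	Phe
R	156.10111	Arg
Y	163.06333	Tyr
W	186.07931	Trp
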