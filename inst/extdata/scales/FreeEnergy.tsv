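# Free energy of solution in water (AAindex CHAM820102 values, kcal/mol).
letter	value
A	-0.368
R	-1.03
N	0.0
D	2.06
C	4.53
Q	0.731
E	1.77
G	-0.525
H	0.0
I	0.791
L	1.07
K	0.0
M	0.656
F	1.06
P	-2.24
S	-0.524
T	0.0
W	1.60
Y	4.91
V	0.401
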