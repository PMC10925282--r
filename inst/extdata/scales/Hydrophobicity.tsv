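# Normalized hydrophobicity scale (AAindex CIDH920105 values).
letter	value
A	0.02
R	-0.42
N	-0.77
D	-1.04
C	0.77
Q	-1.10
E	-1.14
G	-0.80
H	0.26
I	1.81
L	1.14
K	-0.41
M	1.00
F	1.35
P	-0.09
S	-0.97
T	-0.77
W	1.71
Y	1.11
V	1.13
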