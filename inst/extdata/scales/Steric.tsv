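# Steric parameter (graph-shape index, AAindex CHAM810101 values).
letter	value
A	0.52
R	0.68
N	0.76
D	0.76
C	0.62
Q	0.68
E	0.68
G	0.00
H	0.70
I	1.02
L	0.98
K	0.68
M	0.78
F	0.70
P	0.36
S	0.53
T	0.50
W	0.70
Y	0.70
V	0.76
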