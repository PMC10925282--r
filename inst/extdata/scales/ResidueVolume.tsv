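# Residue volume (AAindex BIGC670101 values, A^3).
letter	value
A	52.6
R	109.1
N	75.7
D	68.4
C	68.3
Q	89.7
E	84.7
G	36.3
H	91.9
I	102.0
L	102.0
K	105.1
M	97.7
F	113.9
P	73.6
S	54.9
T	71.2
W	135.4
Y	116.2
V	85.1
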