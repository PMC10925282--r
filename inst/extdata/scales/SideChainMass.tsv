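# Side-chain mass (Da) used by the pseudo amino-acid composition
# sequence-order terms.
letter	value
A	15
R	101
N	58
D	59
C	47
Q	72
E	73
G	1
H	82
I	57
L	57
K	73
M	75
F	91
P	42
S	31
T	45
W	130
Y	107
V	43
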