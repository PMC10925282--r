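# Relative mutability of amino acids (Dayhoff-type, AAindex DAYM780201 values)
# as used by the standard propy autocorrelation descriptor set.
letter	value
A	100
R	65
N	134
D	106
C	20
Q	93
E	102
G	49
H	66
I	96
L	40
K	56
M	94
F	41
P	56
S	120
T	97
W	18
Y	41
V	74
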