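element	radius
# United-atom working radii (implicit hydrogens absorbed into heavy atoms),
# for geometry on hydrogen-free structures. Editable.
H	1.00
C	1.90
N	1.70
O	1.60
F	1.47
P	2.00
S	2.00
CL	1.75
BR	1.85
I	1.98
FE	2.00
ZN	1.39
MG	1.73
MN	1.97
CU	1.40
NA	2.27
K	2.75
SE	1.90
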