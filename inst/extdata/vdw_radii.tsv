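element	radius
C	1.70
N	1.55
O	1.52
S	1.80
P	1.80
SE	1.90
F	1.47
CL	1.75
BR	1.85
I	1.98
NA	2.27
MG	1.73
ZN	1.39
FE	1.52
MN	1.61
HG	1.55
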