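aa	frequency
A	0.07422
C	0.02469
D	0.05363
E	0.05431
F	0.04742
G	0.07415
H	0.02621
I	0.06792
K	0.05816
L	0.09891
M	0.02499
N	0.04465
P	0.03854
Q	0.03426
R	0.05161
S	0.05723
T	0.05089
V	0.07292
W	0.01303
Y	0.03228
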