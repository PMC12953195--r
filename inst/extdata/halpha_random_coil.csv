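residue,atom,shift_ppm
A,HA,4.32
C,HA,4.55
D,HA,4.64
E,HA,4.35
F,HA,4.62
G,HA,3.96
H,HA,4.73
I,HA,4.17
K,HA,4.32
L,HA,4.34
M,HA,4.48
N,HA,4.74
P,HA,4.42
Q,HA,4.34
R,HA,4.34
S,HA,4.47
T,HA,4.35
V,HA,4.12
W,HA,4.66
Y,HA,4.55
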