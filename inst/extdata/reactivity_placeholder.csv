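aa,R
C,1.30
W,1.00
Y,0.77
M,0.65
F,0.41
H,0.29
R,0.26
I,0.14
L,0.10
V,0.065
P,0.050
Q,0.041
K,0.026
E,0.018
A,0.006
D,0.0057
T,0.0038
N,0.0035
S,0.0024
G,0.0006
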