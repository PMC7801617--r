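# SYNTHETIC stand-in for a conformation-specific substitution matrix.
# Scores derived from hydropathy and side-chain volume distances;
# NOT the published CBSM60 values. Used for interface and property tests only.
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A   6  -1   1   1   4   1   1   3   1   2   2   0   3   2   2   3   3   0   1   2
R  -1   6   3   3  -1   4   4   0   4  -1   0   5   1   0   2   1   1   2   3  -1
N   1   3   6   5   1   4   4   2   4  -1  -1   4   1   0   4   3   3   1   2   0
D   1   3   5   6   1   4   4   2   4  -1  -1   4   1   0   4   3   3   1   2   0
C   4  -1   1   1   6   1   1   2   1   3   3   0   3   3   2   3   3   0   1   3
Q   1   4   4   4   1   6   5   1   5   0   0   4   1   0   3   2   3   2   3   0
E   1   4   4   4   1   5   6   1   5   0   0   4   1   0   3   2   3   2   2   0
G   3   0   2   2   2   1   1   6   1   0   0   1   1   0   3   4   4   1   2   1
H   1   4   4   4   1   5   5   1   6   0   1   4   2   1   3   2   3   2   3   0
I   2  -1  -1  -1   3   0   0   0   0   6   5   0   3   3   0   0   1   0   1   4
L   2   0  -1  -1   3   0   0   0   1   5   6   0   4   4   1   1   1   1   1   4
K   0   5   4   4   0   4   4   1   4   0   0   6   1   1   2   1   2   2   3   0
M   3   1   1   1   3   1   1   1   2   3   4   1   6   4   2   2   2   2   2   3
F   2   0   0   0   3   0   0   0   1   3   4   1   4   6   1   1   1   2   2   3
P   2   2   4   4   2   3   3   3   3   0   1   2   2   1   6   4   4   2   3   1
S   3   1   3   3   3   2   2   4   2   0   1   1   2   1   4   6   4   2   2   1
T   3   1   3   3   3   3   3   4   3   1   1   2   2   1   4   4   6   2   3   2
W   0   2   1   1   0   2   2   1   2   0   1   2   2   2   2   2   2   6   4   0
Y   1   3   2   2   1   3   2   2   3   1   1   3   2   2   3   2   3   4   6   1
V   2  -1   0   0   3   0   0   1   0   4   4   0   3   3   1   1   2   0   1   6
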