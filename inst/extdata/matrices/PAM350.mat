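#
# This matrix was produced by "pam" Version 1.0.6 [28-Jul-93]
#
# PAM 350 substitution matrix, scale = ln(2)/5 = 0.138629
#
# Expected score = -0.701, Entropy = 0.186 bits
#
# Lowest score = -10, Highest score = 27
#
    A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   B   Z   X   *
A   2  -1   0   1  -2   0   1   2  -1   0  -2  -1  -1  -4   1   1   1  -7  -4   0   1   0   0 -10
R  -1   7   1  -1  -4   2   0  -2   2  -2  -3   4   0  -5   0   0  -1   4  -5  -3   0   1  -1 -10
N   0   1   2   2  -4   1   2   1   2  -2  -3   1  -2  -4   0   1   1  -5  -3  -2   2   2   0 -10
D   1  -1   2   4  -6   2   4   1   1  -2  -4   1  -3  -6   0   1   0  -8  -5  -2   3   3  -1 -10
C  -2  -4  -4  -6  18  -6  -6  -4  -4  -3  -7  -6  -6  -5  -3   0  -2 -10   1  -2  -5  -6  -3 -10
Q   0   2   1   2  -6   4   3  -1   3  -2  -2   1  -1  -5   1   0   0  -5  -5  -2   2   3   0 -10
E   1   0   2   4  -6   3   4   1   1  -2  -4   0  -2  -6   0   0   0  -8  -5  -2   3   3   0 -10
G   2  -2   1   1  -4  -1   1   5  -2  -2  -4  -1  -3  -6   0   1   1  -8  -6  -1   1   0  -1 -10
H  -1   2   2   1  -4   3   1  -2   7  -2  -2   1  -2  -2   0  -1  -1  -3   0  -2   1   2   0 -10
I   0  -2  -2  -2  -3  -2  -2  -2  -2   5   4  -2   3   2  -2  -1   0  -6   0   4  -2  -2   0 -10
L  -2  -3  -3  -4  -7  -2  -4  -4  -2   4   8  -3   5   3  -3  -3  -2  -2   0   3  -4  -3  -1 -10
K  -1   4   1   1  -6   1   0  -1   1  -2  -3   5   0  -6  -1   0   0  -4  -5  -2   1   1  -1 -10
M  -1   0  -2  -3  -6  -1  -2  -3  -2   3   5   0   6   1  -2  -2  -1  -5  -2   2  -2  -2   0 -10
F  -4  -5  -4  -6  -5  -5  -6  -6  -2   2   3  -6   1  13  -5  -4  -3   1  11  -1  -5  -6  -2 -10
P   1   0   0   0  -3   1   0   0   0  -2  -3  -1  -2  -5   6   1   1  -7  -6  -1   0   0   0 -10
S   1   0   1   1   0   0   0   1  -1  -1  -3   0  -2  -4   1   1   1  -3  -3  -1   1   0   0 -10
T   1  -1   1   0  -2   0   0   1  -1   0  -2   0  -1  -3   1   1   2  -6  -3   0   0   0   0 -10
W  -7   4  -5  -8 -10  -5  -8  -8  -3  -6  -2  -4  -5   1  -7  -3  -6  27   1  -7  -6  -7  -5 -10
Y  -4  -5  -3  -5   1  -5  -5  -6   0   0   0  -5  -2  11  -6  -3  -3   1  14  -2  -4  -5  -2 -10
V   0  -3  -2  -2  -2  -2  -2  -1  -2   4   3  -2   2  -1  -1  -1   0  -7  -2   5  -2  -2   0 -10
B   1   0   2   3  -5   2   3   1   1  -2  -4   1  -2  -5   0   1   0  -6  -4  -2   3   2   0 -10
Z   0   1   2   3  -6   3   3   0   2  -2  -3   1  -2  -6   0   0   0  -7  -5  -2   2   3   0 -10
X   0  -1   0  -1  -3   0   0  -1   0   0  -1  -1   0  -2   0   0   0  -5  -2   0   0   0  -1 -10
* -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10 -10   1
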