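#  Matrix made by matblas from blosum70.iij
#  * column uses minimum score
#  BLOSUM Clustered Scoring Matrix in 1/2 Bit Units
#  Blocks Database = /data/blocks_5.0/blocks.dat
#  Cluster Percentage: >= 70
#  Entropy =   0.8391, Expected =  -0.6313
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V  B  Z  X  *
A  4 -2 -2 -2 -1 -1 -1  0 -2 -2 -2 -1 -1 -2 -1  1  0 -3 -2  0 -2 -1 -1 -5 
R -2  6 -1 -2 -4  1  0 -3  0 -3 -3  2 -2 -3 -2 -1 -1 -3 -2 -3 -1  0 -1 -5 
N -2 -1  6  1 -3  0  0 -1  0 -4 -4  0 -2 -3 -2  0  0 -4 -2 -3  3  0 -1 -5 
D -2 -2  1  6 -4 -1  1 -2 -1 -4 -4 -1 -3 -4 -2  0 -1 -5 -4 -4  4  1 -2 -5 
C -1 -4 -3 -4  9 -3 -4 -3 -4 -1 -2 -4 -2 -2 -3 -1 -1 -3 -3 -1 -4 -4 -2 -5 
Q -1  1  0 -1 -3  6  2 -2  1 -3 -2  1  0 -3 -2  0 -1 -2 -2 -2  0  3 -1 -5 
E -1  0  0  1 -4  2  5 -2  0 -4 -3  1 -2 -4 -1  0 -1 -4 -3 -3  1  4 -1 -5 
G  0 -3 -1 -2 -3 -2 -2  6 -2 -4 -4 -2 -3 -4 -3 -1 -2 -3 -4 -4 -1 -2 -2 -5 
H -2  0  0 -1 -4  1  0 -2  8 -4 -3 -1 -2 -1 -2 -1 -2 -2  2 -3 -1  0 -1 -5 
I -2 -3 -4 -4 -1 -3 -4 -4 -4  4  2 -3  1  0 -3 -3 -1 -3 -1  3 -4 -3 -1 -5 
L -2 -3 -4 -4 -2 -2 -3 -4 -3  2  4 -3  2  0 -3 -3 -2 -2 -1  1 -4 -3 -1 -5 
K -1  2  0 -1 -4  1  1 -2 -1 -3 -3  5 -2 -3 -1  0 -1 -3 -2 -3 -1  1 -1 -5 
M -1 -2 -2 -3 -2  0 -2 -3 -2  1  2 -2  6  0 -3 -2 -1 -2 -1  1 -3 -2 -1 -5 
F -2 -3 -3 -4 -2 -3 -4 -4 -1  0  0 -3  0  6 -4 -3 -2  1  3 -1 -4 -4 -2 -5 
P -1 -2 -2 -2 -3 -2 -1 -3 -2 -3 -3 -1 -3 -4  8 -1 -1 -4 -3 -3 -2 -1 -2 -5 
S  1 -1  0  0 -1  0  0 -1 -1 -3 -3  0 -2 -3 -1  4  1 -3 -2 -2  0  0 -1 -5 
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -2 -1 -1 -2 -1  1  5 -3 -2  0 -1 -1 -1 -5 
W -3 -3 -4 -5 -3 -2 -4 -3 -2 -3 -2 -3 -2  1 -4 -3 -3 11  2 -3 -4 -3 -3 -5 
Y -2 -2 -2 -4 -3 -2 -3 -4  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -2 -3 -2 -2 -5 
V  0 -3 -3 -4 -1 -2 -3 -4 -3  3  1 -3  1 -1 -3 -2  0 -3 -2  4 -3 -3 -1 -5 
B -2 -1  3  4 -4  0  1 -1 -1 -4 -4 -1 -3 -4 -2  0 -1 -4 -3 -3  4  0 -1 -5 
Z -1  0  0  1 -4  3  4 -2  0 -3 -3  1 -2 -4 -1  0 -1 -3 -2 -3  0  4 -1 -5 
X -1 -1 -1 -2 -2 -1 -1 -2 -1 -1 -1 -1 -1 -2 -2 -1 -1 -3 -2 -1 -1 -1 -1 -5 
* -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5 -5  1 
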