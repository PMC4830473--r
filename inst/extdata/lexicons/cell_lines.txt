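# Mutation-like cell-line names (seed list; extend with your own file).
T47D
U87
U2OS
C33A
T98G
H1299
A549
K562
A375
SW480
HT29
MCF7
HCT116
U937
HL60
PC3
DU145
LNCaP
BT474
SKBR3
CAL51
H460
H1975
HCC827
SW620
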