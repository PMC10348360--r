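elem_a,elem_b,order,bde_kj_mol,note
C,C,1,347,typical C-C single
C,C,2,614,typical C=C
C,C,3,839,typical C#C
C,C,4,518,aromatic C:C
C,N,1,305,C-N single
C,N,2,615,C=N
C,N,3,891,C#N
C,N,4,510,aromatic C:N
C,O,1,358,C-O single
C,O,2,745,C=O carbonyl
C,O,4,560,aromatic C:O
C,F,1,485,C-F
C,Cl,1,327,C-Cl
Br,C,1,285,C-Br
C,I,1,213,C-I
C,S,1,259,C-S
C,P,1,264,C-P
B,C,1,356,B-C
N,N,1,163,N-N single
N,N,2,418,N=N
N,N,4,400,aromatic N:N
N,O,1,201,N-O single
N,O,2,607,N=O
O,O,1,146,O-O peroxide
O,P,1,335,P-O
O,S,2,522,S=O
C,S,4,360,aromatic C:S
S,S,1,266,S-S
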