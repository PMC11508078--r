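combined_code,me_code,hours
A,LR,7.00
A,RS,1.00
A,EF,0.85
A,CF,1.25
B,LR,7.00
B,RS,1.00
B,KF,1.28
B,CF,1.02
C,LR,7.00
C,RS,1.00
C,CS,1.07
C,CF,1.43
D,LR,7.00
D,RS,1.00
D,EF,0.85
D,IS,1.15
E,LR,7.00
E,RS,1.00
E,KF,1.28
E,IS,1.02
F,LR,7.00
F,RS,1.00
F,CS,1.07
F,IS,1.43
G,LR,7.00
G,RS,1.00
G,EF,0.85
G,TS,1.15
H,LR,7.00
H,RS,1.00
H,KF,1.28
H,TS,1.02
I,LR,7.00
I,RS,1.00
I,CS,1.07
I,TS,1.43
AA,LR,7.00
AA,RS,1.00
AA,EF,0.85
BB,LR,7.00
BB,RS,1.00
BB,KF,1.28
CC,LR,7.00
CC,RS,1.00
CC,CS,1.07
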