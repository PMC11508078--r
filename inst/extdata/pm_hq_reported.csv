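code,hq_pm25,hq_pm10,hi
A,0.130,0.777,0.907
B,0.140,0.793,0.933
C,0.195,0.853,1.05
D,0.295,0.853,1.15
E,0.306,0.873,1.18
F,0.362,0.935,1.30
G,1.45,1.07,2.52
H,1.47,1.09,2.56
I,1.522,1.15,2.67
AA,0.265,2.38,2.65
BB,0.490,2.65,3.14
CC,0.677,2.96,3.64
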