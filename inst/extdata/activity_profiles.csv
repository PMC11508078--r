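code,ta_h,ef_dpy,el_y,ed_d,at_d,ir_m3pd,bw_kg
A,10.1,104,50,2209,18250,20,60.7
B,10.3,104,50,2253,18250,20,60.7
C,10.5,104,50,2297,18250,20,60.7
D,10.0,104,50,2188,18250,20,60.7
E,10.3,104,50,2253,18250,20,60.7
F,10.5,104,50,2297,18250,20,60.7
G,10.0,104,50,2188,18250,20,60.7
H,10.3,104,50,2253,18250,20,60.7
I,10.5,104,50,2297,18250,20,60.7
AA,8.85,365,50,6730,18250,20,60.7
BB,9.28,365,50,7056,18250,20,60.7
CC,9.07,365,50,6904,18250,20,60.7
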