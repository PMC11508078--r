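code,pollutant,exposure_ugm3,sd_ugm3,add_reported
A,PM2.5,10.6,1.41,0.423
B,PM2.5,11.1,1.37,0.453
C,PM2.5,15.3,2.68,0.632
D,PM2.5,24.2,7.97,0.955
E,PM2.5,24.4,7.68,0.991
F,PM2.5,28.2,55.3,1.17
G,PM2.5,119,7.25,4.70
H,PM2.5,117,53.9,4.75
I,PM2.5,119,52.0,4.93
AA,PM2.5,7.08,1.12,0.86
BB,PM2.5,12.5,3.68,1.59
CC,PM2.5,17.6,1.28,1.42
A,PM10,128,32.7,5.10
B,PM10,128,31.7,5.20
C,PM10,135,31.7,5.60
D,PM10,142,29.8,5.60
E,PM10,141,31.1,5.73
F,PM10,148,29.8,6.13
G,PM10,177,33.3,6.99
H,PM10,175,31.9,7.13
I,PM10,185,28.9,7.53
AA,PM10,129,42.6,15.6
BB,PM10,136,37.3,17.4
CC,PM10,156,40.8,19.4
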