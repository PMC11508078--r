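element,code,mean_ugm3,sd_ugm3
Fe,A,0.075,0.010
Fe,B,0.073,0.02
Fe,C,0.073,0.016
Fe,D,0.055,0.012
Fe,E,0.053,0.015
Fe,F,0.053,0.014
Fe,G,0.055,0.016
Fe,H,0.052,0.015
Fe,I,0.044,0.015
Fe,AA,0.052,0.022
Fe,BB,0.048,0.021
Fe,CC,0.051,0.021
Cu,A,0.0242,0.01
Cu,B,0.0243,0.01
Cu,C,0.0243,0.01
Cu,D,0.024,0.011
Cu,E,0.024,0.086
Cu,F,0.024,0.084
Cu,G,0.024,0.010
Cu,H,0.024,0.012
Cu,I,0.033,0.014
Cu,AA,0.028,0.014
Cu,BB,0.027,0.014
Cu,CC,0.028,0.014
Mn,A,0.179,0.087
Mn,B,0.176,0.070
Mn,C,0.172,0.080
Mn,D,0.179,0.090
Mn,E,0.175,0.086
Mn,F,0.172,0.084
Mn,G,0.180,0.088
Mn,H,0.176,0.086
Mn,I,0.172,0.084
Mn,AA,0.203,0.115
Mn,BB,0.193,0.110
Mn,CC,0.200,0.112
B,A,0.170,0.039
B,B,0.160,0.040
B,C,0.153,0.040
B,D,0.155,0.040
B,E,0.144,0.04
B,F,0.137,0.040
B,G,0.102,0.0400
B,H,0.092,0.040
B,I,0.083,0.040
B,AA,0.110,0.050
B,BB,0.096,0.040
B,CC,0.094,0.050
Zn,A,0.180,0.062
Zn,B,0.182,0.070
Zn,C,0.197,0.060
Zn,D,0.151,0.061
Zn,E,0.154,0.060
Zn,F,0.170,0.058
Zn,G,0.147,0.0640
Zn,H,0.149,0.063
Zn,I,0.162,0.061
Zn,AA,0.158,0.086
Zn,BB,0.156,0.082
Zn,CC,0.182,0.084
Pb,A,0.046,0.021
Pb,B,0.044,0.020
Pb,C,0.045,0.020
Pb,D,0.046,0.021
Pb,E,0.044,0.021
Pb,F,0.045,0.020
Pb,G,0.046,0.020
Pb,H,0.045,0.020
Pb,I,0.052,0.021
Pb,AA,0.051,0.028
Pb,BB,0.048,0.027
Pb,CC,0.051,0.027
Cr,A,0.007,0.002
Cr,B,0.007,0.002
Cr,C,0.008,0.002
Cr,D,0.007,0.002
Cr,E,0.007,0.002
Cr,F,0.008,0.002
Cr,G,0.007,0.020
Cr,H,0.007,0.002
Cr,I,0.008,0.002
Cr,AA,0.007,0.003
Cr,BB,0.007,0.003
Cr,CC,0.008,0.003
Cd,A,0.013,0.005
Cd,B,0.012,0.005
Cd,C,0.014,0.005
Cd,D,0.013,0.005
Cd,E,0.012,0.005
Cd,F,0.014,0.005
Cd,G,0.013,0.005
Cd,H,0.012,0.005
Cd,I,0.014,0.005
Cd,AA,0.014,0.006
Cd,BB,0.013,0.007
Cd,CC,0.015,0.006
Sn,A,0.050,0.023
Sn,B,0.049,0.023
Sn,C,0.049,0.020
Sn,D,0.050,0.024
Sn,E,0.049,0.023
Sn,F,0.049,0.023
Sn,G,0.050,0.024
Sn,H,0.049,0.024
Sn,I,0.049,0.023
Sn,AA,0.056,0.031
Sn,BB,0.053,0.030
Sn,CC,0.055,0.030
As,A,0.016,0.007
As,B,0.016,0.007
As,C,0.018,0.007
As,D,0.016,0.007
As,E,0.016,0.007
As,F,0.017,0.006
As,G,0.016,0.007
As,H,0.016,0.007
As,I,0.018,0.007
As,AA,0.017,0.009
As,BB,0.017,0.009
As,CC,0.020,0.009
Ni,A,0.019,0.008
Ni,B,0.019,0.008
Ni,C,0.023,0.008
Ni,D,0.020,0.008
Ni,E,0.019,0.008
Ni,F,0.022,0.008
Ni,G,0.020,0.008
Ni,H,0.019,0.008
Ni,I,0.022,0.008
Ni,AA,0.021,0.011
Ni,BB,0.020,0.010
Ni,CC,0.024,0.011
Co,A,0.018,0.008
Co,B,0.017,0.007
Co,C,0.017,0.007
Co,D,0.018,0.008
Co,E,0.017,0.007
Co,F,0.017,0.007
Co,G,0.017,0.008
Co,H,0.017,0.008
Co,I,0.017,0.007
Co,AA,0.019,0.010
Co,BB,0.018,0.010
Co,CC,0.018,0.010
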