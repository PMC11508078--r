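element,rfd_inh,rfd_ing,rfd_der,iur,sf,g,abs
Fe,,0.070,,,,,0.010
Cu,0.040,0.040,1.00,,,,0.010
Mn,0.00005,0.140,1.00,,,,0.010
B,,0.200,,,,,0.010
Zn,0.040,0.300,1.00,,,,0.010
Pb,0.0035,0.0035,1.00,0.00008,0.280,1.00,0.010
Cr,0.0004,0.0003,0.025,0.012,0.50,0.025,0.010
Cd,0.00001,0.001,0.025,0.0018,0.640,0.025,0.001
As,0.000015,0.015,1.00,0.043,1.50,1.00,0.030
Ni,0.00005,0.050,0.040,0.0024,0.084,0.040,0.010
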