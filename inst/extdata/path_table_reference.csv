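year,factor,r,P,total_indirect,ind_Rn,ind_Ta,ind_VPD,ind_u2,Rd
2019,Rn,0.952,0.744,0.208,NA,-0.082,0.257,0.033,0.863
2019,Ta,0.811,-0.108,0.919,0.564,NA,0.320,0.035,-0.187
2019,VPD,0.833,0.353,0.481,0.541,-0.098,NA,0.038,0.463
2019,u2,0.672,0.056,0.416,0.445,-0.067,0.038,NA,0.072
2020,Rn,0.888,0.775,0.256,NA,-0.020,0.218,0.058,0.776
2020,Ta,0.731,-0.026,0.933,0.605,NA,0.265,0.064,-0.039
2020,VPD,0.751,0.291,0.630,0.581,-0.024,NA,0.073,0.352
2020,u2,0.615,0.112,0.461,0.403,-0.015,0.073,NA,0.125
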