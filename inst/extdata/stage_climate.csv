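year,stage,Rn,Ta,VPD,u2
2019,initial,114.81,19.19,1.031,0.118
2019,development,125.65,21.26,0.716,0.120
2019,middle,149.92,26.39,1.419,0.102
2019,late,148.44,28.23,1.296,0.089
2020,initial,103.32,18.88,0.791,0.114
2020,development,131.53,20.82,0.700,0.112
2020,middle,142.53,25.48,1.172,0.145
2020,late,154.09,27.03,0.710,0.138
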