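year,stage,et_mm_d
2019,initial,1.30
2020,initial,0.66
2019,middle,3.49
2020,middle,3.90
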