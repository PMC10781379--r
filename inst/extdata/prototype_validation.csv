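measured_C,validation_C,error_C
38.13,38.5,0.37
38.477,38.56,0.083
38.477,38.5,0.023
38.5,39.25,0.75
38.5,39.25,0.75
37.37,37.81,0.44
37.37,37.81,0.44
37.89,37.75,0.14
38.44,37.81,0.63
37.72,37.38,0.34
36.79,37.38,0.59
37.88,37.44,0.44
37.62,37.44,0.18
37.58,36.94,0.64
37.61,36.88,0.73
37.06,36.94,0.12
37.08,36.94,0.14
37.06,36.75,0.31
36.62,36.69,0.07
37.08,36.75,0.33
37.59,36.69,0.9
36.44,36.83,0.39
36.44,36.69,0.25
36.5,36.65,0.15
36.5,36.75,0.25
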