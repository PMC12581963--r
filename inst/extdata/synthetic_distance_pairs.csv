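d1_mm,d2_mm
24,41
54,20
35,35
50.7,56.2
36,55.5
94.6,74.5
40.3,55.8
92,43.4
89.7,42.1
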