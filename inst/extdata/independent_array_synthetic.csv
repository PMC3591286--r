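label,x,y
NEST,0,-1.4
F1,0.0170,0.3621
F2,-0.2069,0.3182
F3,-0.3951,0.1154
F4,-0.4451,-0.1356
F5,-0.1946,-0.2937
F6,-0.0002,-0.4637
F7,0.2900,-0.3713
F8,0.4140,-0.0993
F9,0.4025,0.1223
F10,0.1819,0.2752
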