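label,x,y
NEST,0,-1.4
F1,0.0000,0.1500
F2,-0.1427,0.0464
F3,-0.0882,-0.1214
F4,0.0882,-0.1214
F5,0.1427,0.0464
F6,-0.2645,0.3641
F7,-0.4280,-0.1391
F8,0.0000,-0.4500
F9,0.4280,-0.1391
F10,0.2645,0.3641
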