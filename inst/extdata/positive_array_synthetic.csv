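label,x,y
NEST,0,-1.4
F1,0.0000,0.4000
F2,-0.2351,0.3236
F3,-0.3804,0.1236
F4,-0.3804,-0.1236
F5,-0.2351,-0.3236
F6,0.0000,-0.4000
F7,0.2351,-0.3236
F8,0.3804,-0.1236
F9,0.3804,0.1236
F10,0.2351,0.3236
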