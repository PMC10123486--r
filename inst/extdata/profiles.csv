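label,muA,nuA,muB,nuB
Profile 1,0.5,0.5,0.4,0.55
Profile 2,0.3,0.6,0.4,0.55
Profile 3,0.2,0.4,0.4,0.45
Profile 4,0.6,0.4,0.4,0.45
Profile 5,0.4,0.4,0.5,0.5
Profile 6,0.6,0.4,0.5,0.5
Profile 7,0.3,0.3,0.2,0.2
Profile 8,0.4,0.5,0.5,0.4
Profile 9,0,0,1,0
Profile 10,0,0,0.5,0.5
Profile 11,0.1,0.3,0.2,0.4
Profile 12,0.2,0.5,0.3,0.7
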