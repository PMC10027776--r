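variable,x06,x07,x09,x10,x12,x13
x06,1.00,0.73,0.70,0.17,0.11,0.21
x07,0.73,1.00,0.72,0.10,0.14,0.23
x09,0.70,0.72,1.00,0.12,0.15,0.21
x10,0.17,0.10,0.12,1.00,0.49,0.34
x12,0.11,0.14,0.15,0.49,1.00,0.45
x13,0.21,0.23,0.21,0.34,0.45,1.00
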