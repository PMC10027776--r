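block,variable,r_xx
verbal,x06,0.700
verbal,x07,0.790
verbal,x09,0.860
speed,x10,0.955
speed,x12,0.930
speed,x13,0.885
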