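variable,mean,sd
x06,3.06,1.16
x07,4.34,1.29
x09,2.19,1.10
x10,4.19,1.09
x12,5.53,1.01
x13,5.37,1.01
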