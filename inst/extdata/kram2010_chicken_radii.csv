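label,sensing_radius
green,1.426
red,2.006
blue,2.288
violet,3.553
double,0.786
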