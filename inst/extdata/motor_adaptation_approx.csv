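condition,value
B+,1.00
R+,0.55
B-,0.40
R-,0.15
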