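condition,value
punish_stay,0.10
stay,-0.05
punish_switch,0.05
switch,0.20
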