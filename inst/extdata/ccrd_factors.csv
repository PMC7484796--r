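name,center,step
RL100,7,1
TEC,0.875,0.125
talc,4.375,0.625
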