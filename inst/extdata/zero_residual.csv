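"y","x","e1","e0","g"
1,1,1,0,0.5
0,0,1,0,0.5
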