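"y","x","e1","e0","g"
1.870602,1,0.478462,-0.94608,0.733264
0.582602,1,-2.533329,0.082825,0.678945
2.408238,1,1.747628,-0.289481,0.57367
-1.679676,1,0.144832,0.447006,0.653555
-1.019364,1,0.179848,0.874166,0.366664
0.054704,0,2.273575,0.164726,0.422398
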