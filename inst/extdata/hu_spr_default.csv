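hu,spr
-1200,0.001
-1000,0.001
-800,0.2
-500,0.5
-120,0.88
0,1.0
40,1.04
100,1.07
400,1.25
700,1.42
1200,1.7
2000,2.1
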