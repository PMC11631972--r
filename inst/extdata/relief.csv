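lower,upper
1.1,1.155
1.4,1.470
1.3,1.365
1.7,1.785
1.9,1.995
1.8,1.890
1.6,1.680
2.2,2.310
1.7,1.785
2.7,2.835
4.1,4.305
1.8,1.890
1.5,1.575
1.0,1.050
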