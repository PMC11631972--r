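lower,upper
14.918,15.66390
10.656,11.18880
12.274,12.88770
10.289,10.80345
10.832,11.37360
7.099,7.45395
5.928,6.22440
13.211,13.87155
7.968,8.36640
7.584,7.96320
5.555,5.83275
6.027,6.32835
4.097,4.30185
3.611,3.79155
4.960,5.20800
7.498,7.87290
6.940,7.28700
5.307,5.57235
5.048,5.30040
2.857,2.99985
2.254,2.36670
5.431,5.70255
4.462,4.68510
3.883,4.07715
3.461,3.63405
3.647,3.82935
1.974,2.07270
1.273,1.33665
1.416,1.48680
4.235,4.44675
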