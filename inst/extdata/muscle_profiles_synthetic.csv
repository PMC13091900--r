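"pct","TS","TA","EDL","EHL"
0,0,250,150,80
10,40,180,100,60
20,120,80,60,40
30,250,30,30,25
40,400,10,20,15
50,600,5,15,10
60,850,5,15,10
70,1050,10,20,15
80,900,30,30,25
90,300,60,50,40
100,0,120,80,60
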