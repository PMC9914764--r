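run_id,packaging,rate,response_days
1,NONE,0,5
2,NONE,0.17,7.2
3,NONE,0.33,7.6
4,PBP,0,20.2
5,PBP,0.17,23.2
6,PBP,0.33,24.8
7,VBP,0,21.7
8,VBP,0.17,24.3
9,VBP,0.33,26.1
10,NONE,0,5.4
11,NONE,0,5.6
12,NONE,0,5.8
13,NONE,0,6
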