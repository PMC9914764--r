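run_id,packaging,rate,response_days
1,NONE,0,3
2,NONE,0.3,4
3,NONE,0.7,3.7
4,PBP,0,8
5,PBP,0.3,7.7
6,PBP,0.7,7.2
7,VBP,0,7
8,VBP,0.3,6.6
9,VBP,0.7,5
10,NONE,0,2.9
11,NONE,0,3.1
12,NONE,0,2.8
13,NONE,0,3.2
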