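run_id,packaging,rate,response_days
1,NONE,0,3
2,NONE,0.17,4.2
3,NONE,0.33,4.7
4,PBP,0,7.9
5,PBP,0.17,8.4
6,PBP,0.33,9.1
7,VBP,0,6.9
8,VBP,0.17,7.3
9,VBP,0.33,7.9
10,NONE,0,3.1
11,NONE,0,2.9
12,NONE,0,3.2
13,NONE,0,2.8
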