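0,1,2,3,4,5
112,96,101,48,22,16
135,125,108,44,19,12
141,108,91,55,23,16
119,117,99,60,18,10
139,120,117,37,26,11
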