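time,status
90,1
890,0
142,1
1037,1
150,1
1090,0
269,1
1113,0
291,1
1153,1
468,0
1297,1
680,1
1429,1
837,1
1577,0
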