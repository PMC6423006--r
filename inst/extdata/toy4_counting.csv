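id,start,stop,status,stratum,x,z
1,0.00,0.50,1,1,1,0
1,0.50,1.00,0,2,1,0
2,0.00,1.00,0,1,1,0
3,0.00,0.25,1,1,0,0
3,0.25,0.75,1,2,0,0
3,0.75,1.00,0,3,0,0
4,0.00,1.00,0,1,0,0
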