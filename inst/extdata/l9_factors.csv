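factor,unit,level1,level2,level3
MR,mol alcohol per mol acid,1:1,1:5,1:9
Cat,%,5,10,15
BL,%,20,50,80
t,h,48,72,96
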