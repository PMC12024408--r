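breed,rp_size,h2,method,density,accuracy
A,8000,0.5,PBLUP,50k,0.5909
A,8000,0.5,PBLUP,770k,0.6338
B,12000,0.7,PBLUP,50k,0.6956
B,12000,0.7,PBLUP,770k,0.7781
C,15000,0.3,PBLUP,50k,0.6162
C,15000,0.3,PBLUP,770k,0.6587
A,8000,0.5,GBLUP,50k,0.7214
A,8000,0.5,GBLUP,770k,0.7204
B,12000,0.7,GBLUP,50k,0.8008
B,12000,0.7,GBLUP,770k,0.8106
C,15000,0.3,GBLUP,50k,0.6648
C,15000,0.3,GBLUP,770k,0.6643
A,8000,0.5,wGBLUP,50k,0.6919
A,8000,0.5,wGBLUP,770k,0.7360
B,5000,0.3,wGBLUP,50k,0.6053
B,5000,0.3,wGBLUP,770k,0.7441
C,12000,0.7,wGBLUP,50k,0.7750
C,12000,0.7,wGBLUP,770k,0.8453
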