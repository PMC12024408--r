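breed,rp_size,h2,method,density,accuracy
A,5000,0.3,PBLUP,50k,0.5609333
A,5000,0.3,GBLUP,50k,0.6085367
A,5000,0.3,wGBLUP,50k,0.6289896
A,5000,0.3,PBLUP,770k,0.5793174
A,5000,0.3,GBLUP,770k,0.6243117
A,5000,0.3,wGBLUP,770k,0.6543064
A,5000,0.5,PBLUP,50k,0.6018924
A,5000,0.5,GBLUP,50k,0.703766
A,5000,0.5,wGBLUP,50k,0.7018991
A,5000,0.5,PBLUP,770k,0.6524662
A,5000,0.5,GBLUP,770k,0.7065225
A,5000,0.5,wGBLUP,770k,0.7386434
A,5000,0.7,PBLUP,50k,0.6658209
A,5000,0.7,GBLUP,50k,0.7908608
A,5000,0.7,wGBLUP,50k,0.781666
A,5000,0.7,PBLUP,770k,0.6588115
A,5000,0.7,GBLUP,770k,0.7497605
A,5000,0.7,wGBLUP,770k,0.8060416
A,8000,0.3,PBLUP,50k,0.5639306
A,8000,0.3,GBLUP,50k,0.6323918
A,8000,0.3,wGBLUP,50k,0.6272176
A,8000,0.3,PBLUP,770k,0.5843689
A,8000,0.3,GBLUP,770k,0.6368854
A,8000,0.3,wGBLUP,770k,0.6608198
A,8000,0.5,PBLUP,50k,0.590504
A,8000,0.5,GBLUP,50k,0.7213553
A,8000,0.5,wGBLUP,50k,0.6919124
A,8000,0.5,PBLUP,770k,0.6338298
A,8000,0.5,GBLUP,770k,0.7204071
A,8000,0.5,wGBLUP,770k,0.7359905
A,8000,0.7,PBLUP,50k,0.6403381
A,8000,0.7,GBLUP,50k,0.7882723
A,8000,0.7,wGBLUP,50k,0.7673341
A,8000,0.7,PBLUP,770k,0.646572
A,8000,0.7,GBLUP,770k,0.7690514
A,8000,0.7,wGBLUP,770k,0.8011734
A,12000,0.3,PBLUP,50k,0.5797459
A,12000,0.3,GBLUP,50k,0.6691037
A,12000,0.3,wGBLUP,50k,0.6550116
A,12000,0.3,PBLUP,770k,0.6209803
A,12000,0.3,GBLUP,770k,0.6783403
A,12000,0.3,wGBLUP,770k,0.6995511
A,12000,0.5,PBLUP,50k,0.5835927
A,12000,0.5,GBLUP,50k,0.7372556
A,12000,0.5,wGBLUP,50k,0.6898773
A,12000,0.5,PBLUP,770k,0.6443724
A,12000,0.5,GBLUP,770k,0.7414165
A,12000,0.5,wGBLUP,770k,0.7533543
A,12000,0.7,PBLUP,50k,0.5935911
A,12000,0.7,GBLUP,50k,0.7806763
A,12000,0.7,wGBLUP,50k,0.733462
A,12000,0.7,PBLUP,770k,0.652524
A,12000,0.7,GBLUP,770k,0.7937998
A,12000,0.7,wGBLUP,770k,0.8052261
A,15000,0.3,PBLUP,50k,0.5963547
A,15000,0.3,GBLUP,50k,0.7011606
A,15000,0.3,wGBLUP,50k,0.6717033
A,15000,0.3,PBLUP,770k,0.6431027
A,15000,0.3,GBLUP,770k,0.7049134
A,15000,0.3,wGBLUP,770k,0.7192473
A,15000,0.5,PBLUP,50k,0.5854196
A,15000,0.5,GBLUP,50k,0.750636
A,15000,0.5,wGBLUP,50k,0.684855
A,15000,0.5,PBLUP,770k,0.6465078
A,15000,0.5,GBLUP,770k,0.7560124
A,15000,0.5,wGBLUP,770k,0.7554457
A,15000,0.7,PBLUP,50k,0.6052722
A,15000,0.7,GBLUP,50k,0.7941701
A,15000,0.7,wGBLUP,50k,0.7355052
A,15000,0.7,PBLUP,770k,0.6588932
A,15000,0.7,GBLUP,770k,0.7974239
A,15000,0.7,wGBLUP,770k,0.803195
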