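sex,dms,age
M,0,1.9569
M,2.5,2.1192
M,5,2.2922
M,7.5,2.4761
M,10,2.6712
M,12.5,2.8774
M,15,3.095
M,17.5,3.3236
M,20,3.5631
M,22.5,3.8133
M,25,4.0735
M,27.5,4.3432
M,30,4.6217
M,32.5,4.9081
M,35,5.2014
M,37.5,5.5006
M,40,5.8045
M,42.5,6.1117
M,45,6.421
M,47.5,6.731
M,50,7.0403
M,52.5,7.3476
M,55,7.6515
M,57.5,7.9508
M,60,8.2442
M,62.5,8.5308
M,65,8.8095
M,67.5,9.0794
M,70,9.3398
M,72.5,9.5901
M,75,9.8298
M,77.5,10.0587
M,80,10.2764
M,82.5,10.4829
M,85,10.6782
M,87.5,10.8623
M,90,11.0355
M,92.5,11.1979
M,95,11.35
M,97.5,11.492
M,100,11.6244
F,0,1.8674
F,2.5,2.0372
F,5,2.2194
F,7.5,2.4144
F,10,2.6224
F,12.5,2.8437
F,15,3.0783
F,17.5,3.3259
F,20,3.5865
F,22.5,3.8596
F,25,4.1445
F,27.5,4.4405
F,30,4.7467
F,32.5,5.0618
F,35,5.3845
F,37.5,5.7135
F,40,6.0471
F,42.5,6.3837
F,45,6.7215
F,47.5,7.0588
F,50,7.3939
F,52.5,7.7249
F,55,8.0505
F,57.5,8.3689
F,60,8.6789
F,62.5,8.9792
F,65,9.2688
F,67.5,9.5469
F,70,9.8127
F,72.5,10.0658
F,75,10.3058
F,77.5,10.5326
F,80,10.7461
F,82.5,10.9464
F,85,11.1339
F,87.5,11.3088
F,90,11.4715
F,92.5,11.6225
F,95,11.7623
F,97.5,11.8914
F,100,12.0105
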