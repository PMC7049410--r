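run,dye_conc_ppm,yeast_extract_g_per_L,pH,decolorization_pct,split
1,100,1.75,6.75,90.97,train
2,100,1.75,6.75,87.15,train
3,50,3,6.75,94.9,test
4,150,3,6.75,89.86,train
5,150,1.75,6,77.03,train
6,150,0.5,6.75,54.43,test
7,100,3,6,88.69,train
8,100,0.5,7.5,66.18,train
9,150,1.75,7.5,77.01,test
10,100,1.75,6.75,88.57,train
11,100,3,7.5,89.8,train
12,50,0.5,6.75,79.06,train
13,100,0.5,6,55.31,test
14,50,1.75,6,82.38,train
15,100,1.75,6.75,90.72,train
16,100,1.75,6.75,91.77,test
17,50,1.75,7.5,89.22,train
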