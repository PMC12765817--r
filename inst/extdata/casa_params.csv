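class_code,class_name,NDVImin,NDVImax,epsilon_star
1,ENF,0.023,0.647,0.389
2,EBF,0.023,0.676,0.985
3,DNF,0.023,0.738,0.485
4,DBF,0.023,0.747,0.692
5,MF,0.023,0.702,0.768
6,shrub/grass,0.023,0.636,0.542
7,cropland,0.023,0.634,0.542
8,built,0.023,0.634,0.542
9,other/water,0.023,0.634,0.542
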