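sex,phase,shape,observed,expected_printed,contribution_printed
boy,1,downslope,276,420,49.46
boy,1,early_peak,575,464,26.40
boy,1,early_trough,42,41,0.04
boy,1,peak,154,149,0.14
boy,1,trough,160,164,0.11
boy,1,upslope,305,273,3.68
girl,1,downslope,698,695,0.01
girl,1,early_peak,642,768,20.76
girl,1,early_trough,80,67,2.40
girl,1,peak,272,247,2.48
girl,1,trough,278,272,0.14
girl,1,upslope,532,452,14.08
boy,2,downslope,207,101,110.77
boy,2,early_peak,78,112,10.20
boy,2,early_trough,4,10,3.42
boy,2,peak,10,36,18.75
boy,2,trough,55,40,6.05
boy,2,upslope,10,66,47.31
girl,2,downslope,152,116,10.87
girl,2,early_peak,178,129,18.92
girl,2,early_trough,3,11,6.07
girl,2,peak,38,41,0.28
girl,2,trough,28,46,6.74
girl,2,upslope,20,76,41.01
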