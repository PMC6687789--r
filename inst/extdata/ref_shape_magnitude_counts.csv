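shape,magnitude,sex,phase,observed,expected_printed,contribution_printed
early_peak,small,boy,1,291,261,3.4
early_peak,small,boy,2,58,60,0.1
early_peak,small,girl,1,335,422,18.0
early_peak,small,girl,2,130,70,51.0
early_peak,large,boy,1,284,212,24.8
early_peak,large,boy,2,20,49,17.1
early_peak,large,girl,1,307,342,3.5
early_peak,large,girl,2,48,57,1.4
peak,small,boy,1,101,112,1.1
peak,small,boy,2,10,26,9.8
peak,small,girl,1,206,182,3.3
peak,small,girl,2,33,30,0.3
peak,large,boy,1,53,40,4.4
peak,large,boy,2,0,9,9.2
peak,large,girl,1,66,64,0.0
peak,large,girl,2,5,11,3.0
downslope,small,boy,1,198,268,18.4
downslope,small,boy,2,83,62,7.1
downslope,small,girl,1,478,434,4.6
downslope,small,girl,2,77,72,0.3
downslope,large,boy,1,78,160,41.7
downslope,large,boy,2,124,37,205.8
downslope,large,girl,1,220,258,5.5
downslope,large,girl,2,75,43,24.1
upslope,small,boy,1,166,167,0.0
upslope,small,boy,2,7,39,25.8
upslope,small,girl,1,328,269,12.9
upslope,small,girl,2,18,45,16.0
upslope,large,boy,1,139,112,6.7
upslope,large,boy,2,3,26,20.2
upslope,large,girl,1,204,180,3.1
upslope,large,girl,2,2,30,26.1
trough,small,boy,1,114,110,0.2
trough,small,boy,2,14,25,5.1
trough,small,girl,1,199,177,2.6
trough,small,girl,2,15,29,7.1
trough,medium,boy,1,43,47,0.3
trough,medium,boy,2,24,11,16.0
trough,medium,girl,1,70,76,0.4
trough,medium,girl,2,9,13,1.0
trough,large,boy,1,3,11,5.4
trough,large,boy,2,17,2,86.5
trough,large,girl,1,9,17,3.8
trough,large,girl,2,4,3,0.5
early_trough,small,boy,1,31,33,0.2
early_trough,small,boy,2,3,8,2.9
early_trough,small,girl,1,67,54,3.2
early_trough,small,girl,2,3,9,4.0
early_trough,medium,boy,1,9,7,0.5
early_trough,medium,boy,2,1,2,0.2
early_trough,medium,girl,1,12,11,0.0
early_trough,medium,girl,2,0,2,1.9
early_trough,large,boy,1,2,1,1.1
early_trough,large,boy,2,0,0,0.2
early_trough,large,girl,1,1,2,0.2
early_trough,large,girl,2,0,0,0.3
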