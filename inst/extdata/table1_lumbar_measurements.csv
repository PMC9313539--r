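patient_id,group,level,fractured,pdff_percent,failure_displacement_mm,failure_load_N
1,metastasis,L1,FALSE,24.1,1.027,19735
1,metastasis,L2,FALSE,26.2,0.775,13240
1,metastasis,L3,FALSE,27.8,0.911,39470
1,metastasis,L4,FALSE,31.8,0.724,27447
2,metastasis,L1,FALSE,14.4,1.050,29731
2,metastasis,L2,FALSE,10.3,0.708,29447
2,metastasis,L3,FALSE,9.4,0.804,22665
2,metastasis,L4,FALSE,5.6,0.979,50760
3,metastasis,L1,FALSE,7.7,0.884,45616
3,metastasis,L2,FALSE,13.4,0.841,53618
3,metastasis,L3,FALSE,8.8,0.942,53510
3,metastasis,L4,FALSE,9.8,0.864,27663
4,osteoporosis,L1,FALSE,46.0,0.325,4161
4,osteoporosis,L2,TRUE,41.4,0.978,3173
4,osteoporosis,L3,TRUE,35.8,0.769,10248
4,osteoporosis,L4,FALSE,49.4,0.526,3095
5,osteoporosis,L1,FALSE,33.4,0.296,3744
5,osteoporosis,L2,FALSE,38.0,0.369,4108
5,osteoporosis,L3,FALSE,41.6,0.348,4303
5,osteoporosis,L4,TRUE,26.3,0.315,5995
6,osteoporosis,L1,FALSE,41.0,0.221,3235
6,osteoporosis,L2,TRUE,8.1,0.224,6275
6,osteoporosis,L3,FALSE,43.8,0.311,2728
6,osteoporosis,L4,TRUE,38.5,0.257,6024
7,osteoporosis,L1,FALSE,43.9,0.301,2188
7,osteoporosis,L2,FALSE,43.0,0.502,2797
7,osteoporosis,L3,FALSE,48.6,0.605,2611
7,osteoporosis,L4,FALSE,45.5,0.504,2558
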