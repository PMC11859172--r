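model,class,balanced_accuracy
cv,DK,84.7
cv,PK,99
cv,FS,88.9
cv,HS,80.7
cv,CCS,82.9
cv,ACS,94.2
cv,SK,90.8
cv,STP,85.5
cv,STD,88.9
cv,CLS,85.4
cv,SS,93.1
cv,WLK,100
test_segmented,DK,87.5
test_segmented,PK,99.3
test_segmented,FS,89
test_segmented,HS,85.2
test_segmented,CCS,83.3
test_segmented,ACS,94.6
test_segmented,SK,92.3
test_segmented,STP,88
test_segmented,STD,80.6
test_segmented,CLS,86.9
test_segmented,SS,94.3
test_segmented,WLK,99.9
test_sequences,DK,98.8
test_sequences,PK,93.3
test_sequences,FS,78.1
test_sequences,HS,75.4
test_sequences,CCS,93.8
test_sequences,ACS,91.3
test_sequences,SK,97.3
test_sequences,STP,91.3
test_sequences,STD,94.2
test_sequences,CLS,97.9
test_sequences,SS,94.8
test_sequences,WLK,50
validation,DK,78.1
validation,PK,86.5
validation,FS,64.2
validation,HS,66.1
validation,CCS,78.7
validation,ACS,79
validation,SK,92
validation,STP,82.5
validation,STD,88.1
validation,CLS,78.1
validation,SS,71.7
validation,WLK,49.8
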