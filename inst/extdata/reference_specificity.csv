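model,class,specificity
cv,DK,97.8
cv,PK,98.1
cv,FS,96.3
cv,HS,96.6
cv,CCS,97.3
cv,ACS,96.2
cv,SK,98.6
cv,STP,99.5
cv,STD,100
cv,CLS,98.4
cv,SS,98
cv,WLK,100
test_segmented,DK,98.1
test_segmented,PK,98.6
test_segmented,FS,96.4
test_segmented,HS,97.4
test_segmented,CCS,98.2
test_segmented,ACS,97.1
test_segmented,SK,99.2
test_segmented,STP,99.7
test_segmented,STD,100
test_segmented,CLS,97.9
test_segmented,SS,97
test_segmented,WLK,99.7
test_sequences,DK,97.6
test_sequences,PK,99.5
test_sequences,FS,98.2
test_sequences,HS,98.2
test_sequences,CCS,98.4
test_sequences,ACS,98.4
test_sequences,SK,99.5
test_sequences,STP,92.2
test_sequences,STD,98.9
test_sequences,CLS,99.2
test_sequences,SS,97.1
test_sequences,WLK,100
validation,DK,93
validation,PK,93.6
validation,FS,92.8
validation,HS,93.1
validation,CCS,89.5
validation,ACS,92.1
validation,SK,95.7
validation,STP,88.3
validation,STD,99.8
validation,CLS,94.3
validation,SS,89.8
validation,WLK,99.5
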