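"group","sensitivity","specificity","balanced_accuracy"
"Kneeling",80.3,81.3,81
"Squatting",66.1,86.2,76
"Chair Sitting",93.4,81.7,88
"Stooping",76.7,88.3,83
"Standing",76.5,99.8,88
"Floor Sitting",70.7,82.8,77
"WLK",0,99.5,49.8
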