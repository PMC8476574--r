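table,quantity,class,printed
table1,sensitivity,excluded,1.0
table1,sensitivity,ignored,0.56
table1,sensitivity,inflamed,0.8
table1,specificity_paper,excluded,0.72
table1,specificity_paper,ignored,1.0
table1,specificity_paper,inflamed,1.0
table1,accuracy,,0.81
table1,cohort_n,,43
table2,sensitivity,excluded,0.5
table2,sensitivity,ignored,0.75
table2,sensitivity,inflamed,1.0
table2,specificity_paper,excluded,1.0
table2,specificity_paper,ignored,0.75
table2,specificity_paper,inflamed,0.85
table2,accuracy,,0.83
table3,npv,,0.9
table3,ppv,,0.6
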