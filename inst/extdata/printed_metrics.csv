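table,class,metric,printed_pct
table1a,tumor,accuracy,98.19
table1a,tumor,precision,91.85
table1a,tumor,recall,99.83
table1a,tumor,f1,95.67
table1a,calyx,accuracy,78.77
table1a,calyx,precision,43.18
table1a,calyx,recall,19.47
table1a,calyx,f1,26.84
table2a,tumor,accuracy,99.51
table2a,cortex,accuracy,98.96
table2a,medulla,accuracy,99.78
table2a,calyx,accuracy,99.09
table2a,fat,accuracy,99.27
table2a,pelvis,accuracy,99.95
table2a,calyx,as_tumor_rate,1.48
table2b,tumor,accuracy,99.48
table2b,cortex,accuracy,99.58
table2b,medulla,accuracy,99.88
table2b,calyx,accuracy,99.27
table2b,fat,accuracy,99.65
table2b,pelvis,accuracy,99.95
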