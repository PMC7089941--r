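classification,variable,level,group,count
fibrosis,grade,G2,non_Fibrosis,32
fibrosis,grade,G2,Fibrosis,25
fibrosis,grade,G3,non_Fibrosis,245
fibrosis,grade,G3,Fibrosis,170
fibrosis,stage,II,non_Fibrosis,20
fibrosis,stage,II,Fibrosis,4
fibrosis,stage,III-IV,non_Fibrosis,260
fibrosis,stage,III-IV,Fibrosis,195
fibrosis,debulking,Full,non_Fibrosis,60
fibrosis,debulking,Full,Fibrosis,28
fibrosis,debulking,Partial,non_Fibrosis,190
fibrosis,debulking,Partial,Fibrosis,149
fibrosis,platinum_resistance,Sensitive,non_Fibrosis,153
fibrosis,platinum_resistance,Sensitive,Fibrosis,99
fibrosis,platinum_resistance,Resistant,non_Fibrosis,49
fibrosis,platinum_resistance,Resistant,Fibrosis,40
fibrosis,therapy_outcome,Complete,non_Fibrosis,172
fibrosis,therapy_outcome,Complete,Fibrosis,101
fibrosis,therapy_outcome,Partial,non_Fibrosis,59
fibrosis,therapy_outcome,Partial,Fibrosis,59
fibrosis,brca_mutation,No,non_Fibrosis,269
fibrosis,brca_mutation,No,Fibrosis,171
fibrosis,brca_mutation,Yes,non_Fibrosis,49
fibrosis,brca_mutation,Yes,Fibrosis,46
fibrosis,brca1_methylation,No,non_Fibrosis,278
fibrosis,brca1_methylation,No,Fibrosis,190
fibrosis,brca1_methylation,Yes,non_Fibrosis,40
fibrosis,brca1_methylation,Yes,Fibrosis,27
fibrosis,rad51c_methylation,No,non_Fibrosis,312
fibrosis,rad51c_methylation,No,Fibrosis,210
fibrosis,rad51c_methylation,Yes,non_Fibrosis,6
fibrosis,rad51c_methylation,Yes,Fibrosis,7
fibrosis,lst,Low,non_Fibrosis,147
fibrosis,lst,Low,Fibrosis,89
fibrosis,lst,High,non_Fibrosis,171
fibrosis,lst,High,Fibrosis,127
fibrosis,ploidy,2,non_Fibrosis,104
fibrosis,ploidy,2,Fibrosis,83
fibrosis,ploidy,>=4,non_Fibrosis,214
fibrosis,ploidy,>=4,Fibrosis,133
dimp,grade,G2,D,13
dimp,grade,G2,I,9
dimp,grade,G2,M,17
dimp,grade,G2,P,18
dimp,grade,G3,D,116
dimp,grade,G3,I,93
dimp,grade,G3,M,83
dimp,grade,G3,P,116
dimp,stage,II,D,5
dimp,stage,II,I,12
dimp,stage,II,M,1
dimp,stage,II,P,6
dimp,stage,III-IV,D,129
dimp,stage,III-IV,I,92
dimp,stage,III-IV,M,101
dimp,stage,III-IV,P,126
dimp,debulking,Full,D,33
dimp,debulking,Full,I,17
dimp,debulking,Full,M,10
dimp,debulking,Full,P,28
dimp,debulking,Partial,D,90
dimp,debulking,Partial,I,70
dimp,debulking,Partial,M,81
dimp,debulking,Partial,P,91
dimp,platinum_resistance,Sensitive,D,70
dimp,platinum_resistance,Sensitive,I,54
dimp,platinum_resistance,Sensitive,M,53
dimp,platinum_resistance,Sensitive,P,73
dimp,platinum_resistance,Resistant,D,30
dimp,platinum_resistance,Resistant,I,15
dimp,platinum_resistance,Resistant,M,18
dimp,platinum_resistance,Resistant,P,25
dimp,therapy_outcome,Complete,D,78
dimp,therapy_outcome,Complete,I,60
dimp,therapy_outcome,Complete,M,49
dimp,therapy_outcome,Complete,P,85
dimp,therapy_outcome,Partial,D,34
dimp,therapy_outcome,Partial,I,27
dimp,therapy_outcome,Partial,M,30
dimp,therapy_outcome,Partial,P,25
dimp,brca_mutation,No,D,118
dimp,brca_mutation,No,I,103
dimp,brca_mutation,No,M,94
dimp,brca_mutation,No,P,124
dimp,brca_mutation,Yes,D,30
dimp,brca_mutation,Yes,I,26
dimp,brca_mutation,Yes,M,24
dimp,brca_mutation,Yes,P,14
dimp,brca1_methylation,No,D,127
dimp,brca1_methylation,No,I,110
dimp,brca1_methylation,No,M,101
dimp,brca1_methylation,No,P,128
dimp,brca1_methylation,Yes,D,21
dimp,brca1_methylation,Yes,I,19
dimp,brca1_methylation,Yes,M,17
dimp,brca1_methylation,Yes,P,10
dimp,rad51c_methylation,No,D,144
dimp,rad51c_methylation,No,I,124
dimp,rad51c_methylation,No,M,115
dimp,rad51c_methylation,No,P,137
dimp,rad51c_methylation,Yes,D,4
dimp,rad51c_methylation,Yes,I,5
dimp,rad51c_methylation,Yes,M,3
dimp,rad51c_methylation,Yes,P,1
dimp,lst,Low,D,62
dimp,lst,Low,I,43
dimp,lst,Low,M,48
dimp,lst,Low,P,82
dimp,lst,High,D,86
dimp,lst,High,I,86
dimp,lst,High,M,70
dimp,lst,High,P,56
dimp,ploidy,2,D,71
dimp,ploidy,2,I,39
dimp,ploidy,2,M,46
dimp,ploidy,2,P,31
dimp,ploidy,>=4,D,77
dimp,ploidy,>=4,I,90
dimp,ploidy,>=4,M,72
dimp,ploidy,>=4,P,107
lst,grade,G2,LST_low,27
lst,grade,G2,LST_high,30
lst,grade,G3,LST_low,189
lst,grade,G3,LST_high,224
lst,stage,II,LST_low,8
lst,stage,II,LST_high,16
lst,stage,III-IV,LST_low,210
lst,stage,III-IV,LST_high,243
lst,debulking,Full,LST_low,39
lst,debulking,Full,LST_high,51
lst,debulking,Partial,LST_low,158
lst,debulking,Partial,LST_high,177
lst,platinum_resistance,Sensitive,LST_low,71
lst,platinum_resistance,Sensitive,LST_high,124
lst,platinum_resistance,Resistant,LST_low,55
lst,platinum_resistance,Resistant,LST_high,34
lst,therapy_outcome,Complete,LST_low,111
lst,therapy_outcome,Complete,LST_high,164
lst,therapy_outcome,Partial,LST_low,59
lst,therapy_outcome,Partial,LST_high,58
lst,brca_mutation,No,LST_low,229
lst,brca_mutation,No,LST_high,217
lst,brca_mutation,Yes,LST_low,9
lst,brca_mutation,Yes,LST_high,86
lst,brca1_methylation,No,LST_low,238
lst,brca1_methylation,No,LST_high,235
lst,brca1_methylation,Yes,LST_low,0
lst,brca1_methylation,Yes,LST_high,68
lst,rad51c_methylation,No,LST_low,238
lst,rad51c_methylation,No,LST_high,290
lst,rad51c_methylation,Yes,LST_low,0
lst,rad51c_methylation,Yes,LST_high,13
lst,fibrosis,non_Fibrosis,LST_low,147
lst,fibrosis,non_Fibrosis,LST_high,171
lst,fibrosis,Fibrosis,LST_low,89
lst,fibrosis,Fibrosis,LST_high,127
lst,ploidy,2,LST_low,41
lst,ploidy,2,LST_high,150
lst,ploidy,>=4,LST_low,197
lst,ploidy,>=4,LST_high,153
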