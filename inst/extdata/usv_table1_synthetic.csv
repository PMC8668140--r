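subject_id,sex,condition,min55_1,min55_2,min55_3,min55_4,min55_5,min55_6,min55_7,min55_8,min55_9,min55_10,min22_1,min22_2,min22_3,min22_4,min22_5,min22_6,min22_7,min22_8,min22_9,min22_10
T1_COT_only22_F01,F,COT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_COT_only22_F02,F,COT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,3,2,3
T1_COT_both_F01,F,COT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,3
T1_COT_both_F02,F,COT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3,2,3
T1_COT_both_F03,F,COT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3
T1_COT_only55_F01,F,COT,12,13,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_COT_only55_M01,M,COT,12,13,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_COT_only55_M02,M,COT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_COT_none_F01,F,COT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_COT_none_F02,F,COT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_COT_none_M01,M,COT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_COT_none_M02,M,COT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BOT_only22_F01,F,BOT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_BOT_only22_F02,F,BOT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,3,2,3
T1_BOT_only22_F03,F,BOT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,0,3
T1_BOT_only22_M01,M,BOT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_BOT_both_F01,F,BOT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,3
T1_BOT_both_M01,M,BOT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,3
T1_BOT_only55_F01,F,BOT,12,13,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BOT_only55_F02,F,BOT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_F03,F,BOT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_F04,F,BOT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_F05,F,BOT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_F06,F,BOT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M01,M,BOT,12,13,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M02,M,BOT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M03,M,BOT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M04,M,BOT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M05,M,BOT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M06,M,BOT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_only55_M07,M,BOT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BOT_none_F01,F,BOT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BOT_none_F02,F,BOT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BOT_none_M01,M,BOT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BOT_none_M02,M,BOT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BLT_only22_F01,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_only22_F02,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,3,2,3
T1_BLT_only22_F03,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,0,3
T1_BLT_only22_F04,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_only22_F05,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,3,2,3
T1_BLT_only22_F06,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,0,3
T1_BLT_only22_F07,F,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_only22_M01,M,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_only22_M02,M,BLT,5,0,5,0,5,0,5,0,5,0,0,0,0,0,0,0,0,3,2,3
T1_BLT_both_F01,F,BLT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_both_F02,F,BLT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3,2,3
T1_BLT_both_F03,F,BLT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3
T1_BLT_both_F04,F,BLT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_both_F05,F,BLT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3,2,3
T1_BLT_both_F06,F,BLT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3
T1_BLT_both_M01,M,BLT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,3
T1_BLT_both_M02,M,BLT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3,2,3
T1_BLT_both_M03,M,BLT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3
T1_BLT_only55_F01,F,BLT,12,13,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BLT_only55_F02,F,BLT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BLT_only55_M01,M,BLT,12,13,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BLT_only55_M02,M,BLT,12,13,14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BLT_only55_M03,M,BLT,12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BLT_only55_M04,M,BLT,12,13,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
T1_BLT_none_F01,F,BLT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BLT_none_F02,F,BLT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BLT_none_M01,M,BLT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
T1_BLT_none_M02,M,BLT,4,4,4,4,4,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
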