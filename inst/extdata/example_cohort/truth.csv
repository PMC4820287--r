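subject_id,archetype,expected_label,expected_case_type,expected_exclusion_reason,true_case
S00001,TYPE1_CASE,CASE,1,NA,TRUE
S00002,TYPE1_CASE,CASE,1,NA,TRUE
S00003,TYPE1_CASE,CASE,1,NA,TRUE
S00004,TYPE1_CASE,CASE,1,NA,TRUE
S00005,TYPE1_CASE,CASE,1,NA,TRUE
S00006,TYPE1_CASE,CASE,1,NA,TRUE
S00007,TYPE2_CASE,CASE,2,NA,TRUE
S00008,TYPE2_CASE,CASE,2,NA,TRUE
S00009,TYPE2_CASE,CASE,2,NA,TRUE
S00010,TYPE2_CASE,CASE,2,NA,TRUE
S00011,TYPE2_CASE,CASE,2,NA,TRUE
S00012,TYPE2_CASE,CASE,2,NA,TRUE
S00013,TYPE3_CASE,CASE,3,NA,TRUE
S00014,TYPE3_CASE,CASE,3,NA,TRUE
S00015,TYPE3_CASE,CASE,3,NA,TRUE
S00016,TYPE3_CASE,CASE,3,NA,TRUE
S00017,TYPE3_CASE,CASE,3,NA,TRUE
S00018,TYPE3_CASE,CASE,3,NA,TRUE
S00019,PHENOCOPY,EXCLUDED,NA,PHENOCOPY,FALSE
S00020,PHENOCOPY,EXCLUDED,NA,PHENOCOPY,FALSE
S00021,PHENOCOPY,EXCLUDED,NA,PHENOCOPY,FALSE
S00022,PHENOCOPY,EXCLUDED,NA,PHENOCOPY,FALSE
S00023,PHENOCOPY,EXCLUDED,NA,PHENOCOPY,FALSE
S00024,PHENOCOPY,EXCLUDED,NA,PHENOCOPY,FALSE
S00025,YOUNG_AAA,EXCLUDED,NA,AAA_ONSET_AT_OR_UNDER_MIN_AGE,FALSE
S00026,YOUNG_AAA,EXCLUDED,NA,AAA_ONSET_AT_OR_UNDER_MIN_AGE,FALSE
S00027,YOUNG_AAA,EXCLUDED,NA,AAA_ONSET_AT_OR_UNDER_MIN_AGE,FALSE
S00028,YOUNG_AAA,EXCLUDED,NA,AAA_ONSET_AT_OR_UNDER_MIN_AGE,FALSE
S00029,YOUNG_AAA,EXCLUDED,NA,AAA_ONSET_AT_OR_UNDER_MIN_AGE,FALSE
S00030,YOUNG_AAA,EXCLUDED,NA,AAA_ONSET_AT_OR_UNDER_MIN_AGE,FALSE
S00031,SINGLE_CODE_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00032,SINGLE_CODE_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00033,SINGLE_CODE_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00034,SINGLE_CODE_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00035,SINGLE_CODE_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00036,SINGLE_CODE_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00037,NONSPECIALTY_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00038,NONSPECIALTY_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00039,NONSPECIALTY_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00040,NONSPECIALTY_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00041,NONSPECIALTY_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00042,NONSPECIALTY_AAA,EXCLUDED,NA,UNCONFIRMED_AAA_CODE,FALSE
S00043,STALE_RECORD,EXCLUDED,NA,NO_RECENT_ENCOUNTER,FALSE
S00044,STALE_RECORD,EXCLUDED,NA,NO_RECENT_ENCOUNTER,FALSE
S00045,STALE_RECORD,EXCLUDED,NA,NO_RECENT_ENCOUNTER,FALSE
S00046,STALE_RECORD,EXCLUDED,NA,NO_RECENT_ENCOUNTER,FALSE
S00047,STALE_RECORD,EXCLUDED,NA,NO_RECENT_ENCOUNTER,FALSE
S00048,STALE_RECORD,EXCLUDED,NA,NO_RECENT_ENCOUNTER,FALSE
S00049,CLEAN_CONTROL,CONTROL,NA,NA,FALSE
S00050,CLEAN_CONTROL,CONTROL,NA,NA,FALSE
S00051,CLEAN_CONTROL,CONTROL,NA,NA,FALSE
S00052,CLEAN_CONTROL,CONTROL,NA,NA,FALSE
S00053,CLEAN_CONTROL,CONTROL,NA,NA,FALSE
S00054,CLEAN_CONTROL,CONTROL,NA,NA,FALSE
S00055,NOISY_CONTROL,CONTROL,NA,NA,FALSE
S00056,NOISY_CONTROL,CONTROL,NA,NA,FALSE
S00057,NOISY_CONTROL,CONTROL,NA,NA,FALSE
S00058,NOISY_CONTROL,CONTROL,NA,NA,FALSE
S00059,NOISY_CONTROL,CONTROL,NA,NA,FALSE
S00060,NOISY_CONTROL,CONTROL,NA,NA,FALSE
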