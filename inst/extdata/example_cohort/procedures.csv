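subject_id,event_date,cpt_code,clinic,age_at_event
S00001,2012-03-14,34804,vascular surgery,70
S00002,2012-03-29,35091,vascular surgery,74
S00003,2012-01-24,35103,vascular surgery,79
S00004,2012-09-01,35082,vascular surgery,57
S00005,2012-05-17,34832,vascular surgery,76
S00006,2012-05-09,34802,vascular surgery,58
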