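item_id,phase,polarity,included,scale
q01,after,positive,TRUE,after_scale
q02,after,negative,TRUE,after_scale
q03,after,positive,TRUE,after_scale
q04,after,negative,TRUE,after_scale
q05,after,positive,TRUE,after_scale
q06,after,negative,TRUE,after_scale
q07,after,positive,TRUE,after_scale
q08,after,positive,FALSE,none
q09,after,negative,FALSE,none
q10,during,positive,TRUE,during_scale
q11,during,negative,TRUE,during_scale
q12,during,positive,TRUE,during_scale
q13,during,negative,TRUE,during_scale
q14,during,negative,TRUE,during_scale
q15,during,positive,TRUE,during_scale
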