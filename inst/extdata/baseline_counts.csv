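variable,level,er_negative,er_positive
menopause,pre,46,230
menopause,post,84,513
detection,screening,35,276
detection,symptoms,94,459
detection,unknown,1,8
breast_surgery,conservative,84,501
breast_surgery,mastectomy,46,242
axillary_surgery,dissection,72,344
axillary_surgery,none,0,2
axillary_surgery,sentinel,58,397
histology,ductal,121,643
histology,lobular,1,42
histology,mixed,0,2
histology,non_classified,1,0
histology,special_type,7,56
ki67,negative,4,23
ki67,positive,3,30
ki67,unknown,123,690
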