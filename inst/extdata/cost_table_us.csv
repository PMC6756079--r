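"category","kind","amount_base","amount_2017","variable_share"
"Hospital inpatient stays","direct","90.3","101","0.165"
"Hospital emergency room visits","direct","10.6","11.9","0.165"
"Hospital outpatient or office-based provider visits","direct","46.3","51.8","0.165"
"Home healthcare","direct","19.6","21.9","1"
"Prescribed medicines","direct","32.3","36.1","1"
"Lost productivity/mortality","indirect","130.5","145.9","1"
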