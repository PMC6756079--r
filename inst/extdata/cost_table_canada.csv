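"category","kind","amount_base","amount_2017","variable_share"
"Hospitals","direct","6128","6434","0.165"
"Drugs","direct","4957","5205","1"
"Physicians","direct","1.91e+03","2005","1"
"Formal caregiving","direct","5.1","5.4","1"
"Mortality","indirect","130.9","137.4","1"
"Morbidity and long-term caring","indirect","513.3","539","1"
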