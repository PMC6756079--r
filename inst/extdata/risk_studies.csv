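"name","n","rr_lm","lo_lm","hi_lm","rr_lh","lo_lh","hi_lh"
"Ahmad 2018 (Women's Health Study)",25994,"0.77","0.67","0.9","0.72","0.61","0.86"
"Shikany 2018 (REGARDS)",3562,"0.91","0.76","1.1","0.78","0.62","0.98"
"George 2014 (WHI OS)",63805,"0.82","0.7","0.97","0.79","0.67","0.94"
"Gardener 2011 (NOMAS)",1559,"0.72","0.54","0.96","0.75","0.56","0.99"
"Fung 2009 (Nurses' Health)",1399,"0.87","0.77","0.99","0.71","0.62","0.82"
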