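"name","n","scale","low","medium","high"
"Ahmad 2018 (Women's Health Study)",25994,"9-point","39","36.2","24.8"
"Park 2003 (NHANES III)",4700,"5-point","36.8","31.9","31.3"
"Tsivgoulis 2015 (REGARDS)",20197,"9-point","32.8","41.4","25.8"
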