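daa	dab
DAA*02:01	DAB*02:01
DAA*06:01	DAB*06:01
DAA*01:01	DAB*08:01
DAA*04:01	DAB*07:01
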