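IGHJ1*01	5
IGHJ2*01	8
IGHJ3*01	11
IGHJ4*01	14
IGHJ5*01	5
IGHJ6*01	8
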