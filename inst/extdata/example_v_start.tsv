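IGHV1-1*01	9
IGHV1-1*02	9
IGHV1-2*01	9
IGHV2-1*01	9
IGHV2-1*02	9
IGHV2-2*01	9
IGHV3-1*01	9
IGHV3-2*01	9
IGHV1-3*01	9
IGHV2-4*01	9
IGHV3-5*01	9
IGHV1-6*01	9
IGHV2-7*01	9
IGHV3-8*01	9
IGHV1-9*01	9
IGHV2-10*01	9
IGHV3-11*01	9
IGHV1-12*01	9
IGHV2-13*01	9
IGHV3-14*01	9
IGHV1-15*01	9
IGHV2-16*01	9
IGHV3-17*01	9
IGHV1-18*01	9
IGHV2-19*01	9
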