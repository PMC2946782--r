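>IGHJ1*01
TTTCATGGTTCTTCACATCATAT
>IGHJ2*01
TTAATTTATGGTATCCTCTCTTAACC
>IGHJ3*01
ACTCACTCTAATGGAACAATCACATCCCC
>IGHJ4*01
TTTATTTCATTTTATGGCCCATTTTACTACCC
>IGHJ5*01
TAATCTGGTACAATCAATCTAAA
>IGHJ6*01
CACACCAATGGTTCTCCAAACATATA
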