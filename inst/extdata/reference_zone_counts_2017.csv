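country,zone,n
DE,GREEN,11
DE,YELLOW,2
DE,RED,3
ES,GREEN,3
ES,YELLOW,5
ES,RED,11
FR,GREEN,NA
FR,YELLOW,NA
FR,RED,11
IT,GREEN,16
IT,YELLOW,2
IT,RED,3
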