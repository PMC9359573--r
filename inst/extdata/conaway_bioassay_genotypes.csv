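insecticide,knockdown,LL,LF,FF,SF
permethrin,no,0,0,11,0
permethrin,yes,1,2,9,3
deltamethrin,no,0,0,12,0
deltamethrin,yes,0,4,8,3
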