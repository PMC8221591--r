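gene,region,duration_h,group,mean_dct,sem,n
Arc,CTX,3,sleep,5.16,0.37,4
Arc,CTX,3,SD,3.90,0.19,5
Arc,CTX,6,sleep,2.20,0.26,6
Arc,CTX,6,SD,0.93,0.17,6
Arc,HP,3,sleep,4.29,0.07,4
Arc,HP,3,SD,3.98,0.15,5
Homer1a,CTX,3,sleep,5.11,0.29,4
Homer1a,CTX,3,SD,4.053,0.18,5
Homer1a,HP,3,sleep,5.97,0.09,4
Homer1a,HP,3,SD,5.12,0.232,5
Bdnf,CTX,3,sleep,5.02,0.12,4
Bdnf,CTX,3,SD,4.542,0.10,5
Narp,CTX,3,sleep,5.34,0.05,4
Narp,CTX,3,SD,4.861,0.08,5
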