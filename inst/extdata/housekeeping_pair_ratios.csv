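population,duration_h,region,gene_pair,ratio,fold_change_printed
Camk2a,3,CTX,Actg1/Hprt1,0.98,-1.02
Camk2a,3,HP,Gapdh/Tuba4a,0.90,-1.11
Camk2a,6,CTX,Pgk1/Tbp,0.87,-1.15
Camk2a,6,HP,Gapdh/Tuba4a,0.92,-1.08
PV,3,CTX,Actg1/Hprt1,0.82,-1.22
PV,3,HP,Gapdh/Tuba4a,1.02,1.02
PV,6,CTX,Pgk1/Tbp,0.97,-1.03
PV,6,HP,Gapdh/Tuba4a,1.02,1.02
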