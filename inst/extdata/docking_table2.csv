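component,target,binding_energy
Sodium Danshensu,PPARG,-6.7
Sodium Danshensu,EGFR,-6.5
Sodium Danshensu,ESR2,-6.5
Sodium Danshensu,ESR1,-6.1
Sodium Danshensu,IGF1R,-6.0
Sodium Danshensu,CASP3,-5.5
Sodium Danshensu,JUN,-5.3
Sodium Danshensu,SRC,-4.6
Sodium Danshensu,AR,-4.3
Sodium Danshensu,NFKB1,-4.3
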