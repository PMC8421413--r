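species,concentration_uM
Ala,100
Arg,150
Asn,50
Gln,600
Glu,100
Gly,100
His,100
Ile,200
Leu,200
Lys,200
Met,50
Phe,100
Pro,100
Ser,100
Thr,200
Trp,20
Tyr,100
Val,200
Cys,0
CySS,100
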