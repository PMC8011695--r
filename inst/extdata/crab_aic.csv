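model,aic
Poisson,14301.321
NegBin,9823.639
ZIPoiss,9327.086
ZINegBi,8923.355
HurdNBi,8880.203
PoisNB,9168.129
NBPois,9027.727
OIPoiss,14302.951
OINegBi,12625.047
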