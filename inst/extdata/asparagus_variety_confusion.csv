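class,Backlim,Cumulus,Gijnlim,Grolim
Backlim,41,2,6,7
Cumulus,3,14,3,3
Gijnlim,9,1,31,1
Grolim,3,4,3,19
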