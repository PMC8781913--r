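class,2016,2017
Backlim,33,23
Cumulus,12,11
Gijnlim,22,20
Grolim,18,11
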