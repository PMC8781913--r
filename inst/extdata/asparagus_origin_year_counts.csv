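class,2016,2017,2018
Germany,105,77,31
Greece,14,7,4
Netherlands,10,10,11
Peru,7,4,2
Poland,16,11,8
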