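class,Germany,Greece,Netherlands,Peru,Poland
Germany,196,4,5,0,8
Greece,0,23,0,0,2
Netherlands,5,0,23,0,3
Peru,1,0,0,11,1
Poland,7,2,3,0,23
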