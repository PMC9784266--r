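,gnp,mys,apac,unem,roca,mvta,ssii
Belgium,1,1,1,1,1,1,1
Denmark,1,1,1,1,0,0,1
Finland,1,1,0,0,0,0,1
France,1,1,1,1,1,1,1
Ireland,0,0,0,1,1,1,0
Italy,1,0,1,1,1,1,0
Netherlands,1,1,0,0,0,0,0
Norway,1,1,0,0,0,0,1
Portugal,0,0,1,0,1,1,0
Spain,0,0,1,1,1,1,0
Sweden,1,1,0,0,0,0,1
UK,1,1,0,0,0,0,0
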