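class,parent,duration_s,observations,percent
Rest,,25380,6345,47.1
Forage,,10404,2601,19.3
Root,Forage,2676,669,5.0
Walk,,5780,1445,10.7
Stand,,6672,1668,12.4
Vigilance,Stand,472,118,0.9
Run,,4168,1042,7.7
Trot,Run,2556,639,4.8
Other,,1440,360,2.7
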