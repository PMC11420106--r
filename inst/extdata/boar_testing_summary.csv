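class,parent,duration_s,epochs
Rest,,11008,67
Forage,,7436,343
Root,Forage,1562,98
Walk,,4129,459
Stand,,4590,685
Vigilance,Stand,439,106
Run,,1827,157
Trot,Run,647,106
Other,,1505,389
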