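class,Walk,Other,Rest,Forage,Run,Stand
Walk,36851,2883,0,5514,472,2064
Other,2758,9863,15,5606,1580,3881
Rest,39,253,101077,0,0,3379
Forage,962,1090,0,62545,2361,995
Run,167,788,0,35,13649,173
Stand,508,174,8987,656,209,35409
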