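class,Walk,Other,Rest,Forage,Root,Run,Trot,Stand,Vigilance
Walk,36851,2883,0,4643,871,172,300,1885,179
Other,2758,9863,15,3959,1647,601,979,3334,547
Rest,39,253,101077,0,0,0,0,3330,49
Forage,170,587,0,42458,4415,1,0,457,478
Root,792,503,0,7061,8611,2360,0,55,5
Run,0,129,0,35,0,7164,109,15,0
Trot,167,659,0,0,0,1306,5070,119,39
Stand,434,117,8372,585,64,203,2,27766,2980
Vigilance,74,57,615,7,0,0,4,4547,116
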