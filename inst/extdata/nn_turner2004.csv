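record_type,key,dG37_kcal
stack,CG/GC,-2.4
stack,CC/GG,-3.3
stack,CU/GG,-2.1
stack,CG/GU,-1.4
stack,CU/GA,-2.1
stack,CA/GU,-2.1
stack,GG/CC,-3.3
stack,GC/CG,-3.4
stack,GU/CG,-2.5
stack,GG/CU,-1.5
stack,GU/CA,-2.2
stack,GA/CU,-2.4
stack,GG/UC,-2.1
stack,GC/UG,-2.5
stack,GU/UG,1.3
stack,GG/UU,-0.5
stack,GU/UA,-1.4
stack,GA/UU,-1.3
stack,UG/GC,-1.4
stack,UC/GG,-1.5
stack,UU/GG,-0.5
stack,UG/GU,0.3
stack,UU/GA,-0.6
stack,UA/GU,-1
stack,AG/UC,-2.1
stack,AC/UG,-2.2
stack,AU/UG,-1.4
stack,AG/UU,-0.6
stack,AU/UA,-1.1
stack,AA/UU,-0.9
stack,UG/AC,-2.1
stack,UC/AG,-2.4
stack,UU/AG,-1.3
stack,UG/AU,-1
stack,UU/AA,-0.9
stack,UA/AU,-1.3
init,duplex,4.1
terminal_au,AU_GU_end,0.5
hairpin_loop,3,5.4
hairpin_loop,4,5.6
hairpin_loop,5,5.7
hairpin_loop,6,5.4
hairpin_loop,7,6
hairpin_loop,8,5.5
hairpin_loop,9,6.4
hairpin_loop,10,6.5
hairpin_loop,11,6.6
hairpin_loop,12,6.7
hairpin_loop,13,6.8
hairpin_loop,14,6.9
hairpin_loop,15,6.9
hairpin_loop,16,7
hairpin_loop,17,7.1
hairpin_loop,18,7.1
hairpin_loop,19,7.2
hairpin_loop,20,7.2
hairpin_loop,21,7.3
hairpin_loop,22,7.3
hairpin_loop,23,7.4
hairpin_loop,24,7.4
hairpin_loop,25,7.5
hairpin_loop,26,7.5
hairpin_loop,27,7.5
hairpin_loop,28,7.6
hairpin_loop,29,7.6
hairpin_loop,30,7.7
provenance,turner2004_vienna,NA
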