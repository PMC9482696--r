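joint,specimen,context,axis,max_fe,max_abad,max_lar,min_fe,min_abad,min_lar,printed_range
hip,Sal10,ex_vivo,FE,29,6,-73,-85,24,-97,114
hip,Sal10,ex_vivo,ABAD,-26,57,-52,-4,-70,-36,128
hip,Sal10,ex_vivo,LAR,-42,-55,-13,-60,36,-147,134
hip,Sal12,ex_vivo,FE,-3,-57,-42,-95,0,-62,92
hip,Sal12,ex_vivo,ABAD,-56,49,-115,-26,-58,-30,108
hip,Sal12,ex_vivo,LAR,-42,-46,-12,-58,11,-121,110
hip,Sal13,ex_vivo,FE,43,-4,-80,-88,22,-111,131
hip,Sal13,ex_vivo,ABAD,-15,71,-49,-48,-39,-70,110
hip,Sal13,ex_vivo,LAR,3,52,-12,-9,33,-143,131
hip,Sal14,ex_vivo,FE,43,35,-45,-72,6,-67,115
hip,Sal14,ex_vivo,ABAD,2,63,-98,8,-43,-72,106
hip,Sal14,ex_vivo,LAR,-13,46,-20,5,5,-140,120
hip,Sal22,in_vivo,FE,64,22,-73,-53,10,-56,117
hip,Sal22,in_vivo,ABAD,55,31,-64,-11,-9,-39,40
hip,Sal22,in_vivo,LAR,-10,3,-36,31,-7,-133,96
knee,Sal06,ex_vivo,FE,133,24,5,5,-3,7,128
knee,Sal06,ex_vivo,ABAD,133,26,5,18,-27,0,53
knee,Sal06,ex_vivo,LAR,85,-6,30,8,-7,-35,65
knee,Sal08,ex_vivo,FE,115,-34,13,16,-23,18,99
knee,Sal08,ex_vivo,ABAD,49,16,-15,95,-38,14,53
knee,Sal08,ex_vivo,LAR,54,-6,33,26,-5,-21,54
knee,Sal22,in_vivo,FE,124,17,-17,10,-2,-7,115
knee,Sal22,in_vivo,ABAD,105,22,-18,31,-15,7,37
knee,Sal22,in_vivo,LAR,48,-6,9,109,22,-22,32
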