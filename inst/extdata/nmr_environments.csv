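"element","environment","shift_ppm","note"
"B","B|C:1",40,"surrogate: base + neighbour increments"
"Br","Br|C:1",45,"surrogate: base + neighbour increments"
"C","C",10,"surrogate: base + neighbour increments"
"C","C|B:1",18,"surrogate: base + neighbour increments"
"C","C|Br:1,C:1",37,"surrogate: base + neighbour increments"
"C","C|C:1",15,"surrogate: base + neighbour increments"
"C","C|C:1,C:1",20,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,C:1",25,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,C:1,C:1",30,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,C:1,C:1,C:1",35,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,C:1,C:1,C:1,C:1",40,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,C:1,O:1",53,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,Cl:1",45,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,N:1",38,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,O:1",48,"surrogate: base + neighbour increments"
"C","C|C:1,C:1,O:2",118,"surrogate: base + neighbour increments"
"C","C|C:1,C:3",40,"surrogate: base + neighbour increments"
"C","C|C:1,C:4,C:4",37,"surrogate: base + neighbour increments"
"C","C|C:1,Cl:1",40,"surrogate: base + neighbour increments"
"C","C|C:1,Cl:1,N:1",58,"surrogate: base + neighbour increments"
"C","C|C:1,Cl:1,O:1",68,"surrogate: base + neighbour increments"
"C","C|C:1,F:1",50,"surrogate: base + neighbour increments"
"C","C|C:1,I:1",33,"surrogate: base + neighbour increments"
"C","C|C:1,N:1",33,"surrogate: base + neighbour increments"
"C","C|C:1,N:1,O:1",61,"surrogate: base + neighbour increments"
"C","C|C:1,N:1,O:2",131,"surrogate: base + neighbour increments"
"C","C|C:1,O:1",43,"surrogate: base + neighbour increments"
"C","C|C:1,O:1,O:2",141,"surrogate: base + neighbour increments"
"C","C|C:1,O:2",113,"surrogate: base + neighbour increments"
"C","C|C:2",27.5,"surrogate: base + neighbour increments"
"C","C|C:3",35,"surrogate: base + neighbour increments"
"C","C|C:4,C:4",32,"surrogate: base + neighbour increments"
"C","C|C:4,C:4,C:4",43,"surrogate: base + neighbour increments"
"C","C|C:4,C:4,Cl:1",57,"surrogate: base + neighbour increments"
"C","C|C:4,C:4,N:1",50,"surrogate: base + neighbour increments"
"C","C|C:4,C:4,O:1",60,"surrogate: base + neighbour increments"
"C","C|C:4,N:4",60.6,"surrogate: base + neighbour increments"
"C","C|C:4,O:4",82.6,"surrogate: base + neighbour increments"
"C","C|C:4,S:4",54,"surrogate: base + neighbour increments"
"C","C|I:1",28,"surrogate: base + neighbour increments"
"C","C|N:1",28,"surrogate: base + neighbour increments"
"C","C|N:1,O:2",126,"surrogate: base + neighbour increments"
"C","C|N:2",73,"surrogate: base + neighbour increments"
"C","C|N:3",100,"surrogate: base + neighbour increments"
"C","C|N:4,N:4",89.2,"surrogate: base + neighbour increments"
"C","C|O:1",38,"surrogate: base + neighbour increments"
"C","C|O:1,O:2",136,"surrogate: base + neighbour increments"
"C","C|P:1",22,"surrogate: base + neighbour increments"
"C","C|S:1",25,"surrogate: base + neighbour increments"
"Cl","Cl|C:1",65,"surrogate: base + neighbour increments"
"F","F|C:1",105,"surrogate: base + neighbour increments"
"I","I|C:1",25,"surrogate: base + neighbour increments"
"N","N|C:1",35,"surrogate: base + neighbour increments"
"N","N|C:1,C:1",40,"surrogate: base + neighbour increments"
"N","N|C:1,C:1,C:1",45,"surrogate: base + neighbour increments"
"N","N|C:2",47.5,"surrogate: base + neighbour increments"
"N","N|C:3",55,"surrogate: base + neighbour increments"
"N","N|C:4,C:4",52,"surrogate: base + neighbour increments"
"N","N|N:1",48,"surrogate: base + neighbour increments"
"N","N|O:2",128,"surrogate: base + neighbour increments"
"O","O|C:1",55,"surrogate: base + neighbour increments"
"O","O|C:1,C:1",60,"surrogate: base + neighbour increments"
"O","O|C:2",67.5,"surrogate: base + neighbour increments"
"O","O|C:4,C:4",72,"surrogate: base + neighbour increments"
"O","O|N:2",113,"surrogate: base + neighbour increments"
"O","O|O:1",78,"surrogate: base + neighbour increments"
"P","P|C:1",30,"surrogate: base + neighbour increments"
"S","S|C:1",20,"surrogate: base + neighbour increments"
"S","S|C:1,C:1",25,"surrogate: base + neighbour increments"
"S","S|C:4,C:4",37,"surrogate: base + neighbour increments"
"S","S|S:1",30,"surrogate: base + neighbour increments"
"C","*",10,"element default (fallback)"
"N","*",30,"element default (fallback)"
"O","*",50,"element default (fallback)"
"F","*",100,"element default (fallback)"
"Cl","*",60,"element default (fallback)"
"Br","*",40,"element default (fallback)"
"I","*",20,"element default (fallback)"
"S","*",15,"element default (fallback)"
"P","*",25,"element default (fallback)"
"B","*",35,"element default (fallback)"
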