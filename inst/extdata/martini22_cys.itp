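; cysteine template, Martini 2.2 dialect
[ moleculetype ]
; molname  nrexcl
CYS  1

[ atoms ]
;  id type resnr residue atom cgnr charge
   1 P5    1 CYS   BB      1   0.0000 ; role=backbone
   2 C5    1 CYS   SC1     2   0.0000 ; role=sidechain

[ bonds ]
;  i  j funct length fc
   1  2 1 0.3100 7500.00
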