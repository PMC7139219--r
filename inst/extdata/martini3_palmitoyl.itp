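; palmitoyl tail fragment, Martini 3 dialect (amide-linked third chain)
[ moleculetype ]
; molname  nrexcl
PALM  1

[ atoms ]
;  id type resnr residue atom cgnr charge
   1 C1    1 PALM  C1P     1   0.0000 ; role=tail
   2 C1    1 PALM  C2P     2   0.0000 ; role=tail
   3 C1    1 PALM  C3P     3   0.0000 ; role=tail
   4 C1    1 PALM  C4P     4   0.0000 ; role=tail

[ bonds ]
;  i  j funct length fc
   1  2 1 0.4700 3800.00
   2  3 1 0.4700 3800.00
   3  4 1 0.4700 3800.00

[ angles ]
;  i  j  k funct angle fc
   1  2  3 2 180.00 35.00
   2  3  4 2 180.00 35.00
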