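; POPG template, Martini 3 dialect, with fragment-role annotations
[ moleculetype ]
; molname  nrexcl
POPG  1

[ atoms ]
;  id type resnr residue atom cgnr charge
   1 P4    1 POPG  GL0     1   0.0000 ; role=headgroup
   2 Q5    1 POPG  PO4     2  -1.0000 ; role=phosphate
   3 SN4a  1 POPG  GL1     3   0.0000 ; role=glycerol
   4 N4a   1 POPG  GL2     4   0.0000 ; role=glycerol
   5 C1    1 POPG  C1A     5   0.0000 ; role=tail sn-2 oleoyl
   6 C4h   1 POPG  D2A     6   0.0000 ; role=tail sn-2 oleoyl cis bead
   7 C1    1 POPG  C3A     7   0.0000 ; role=tail sn-2 oleoyl
   8 C1    1 POPG  C4A     8   0.0000 ; role=tail sn-2 oleoyl
   9 C1    1 POPG  C1B     9   0.0000 ; role=tail sn-1 palmitoyl
  10 C1    1 POPG  C2B    10   0.0000 ; role=tail sn-1 palmitoyl
  11 C1    1 POPG  C3B    11   0.0000 ; role=tail sn-1 palmitoyl
  12 C1    1 POPG  C4B    12   0.0000 ; role=tail sn-1 palmitoyl

[ bonds ]
;  i  j funct length fc
   1  2 1 0.4200 1350.00
   2  3 1 0.4200 1350.00
   3  4 1 0.3120 2500.00
   3  5 1 0.4700 5000.00
   5  6 1 0.4700 3800.00
   6  7 1 0.4700 3800.00
   7  8 1 0.4700 3800.00
   4  9 1 0.4700 5000.00
   9 10 1 0.4700 3800.00
  10 11 1 0.4700 3800.00
  11 12 1 0.4700 3800.00

[ angles ]
;  i  j  k funct angle fc
   2  3  4 2 108.00 21.50
   2  3  5 2 139.10 31.20
   3  5  6 2 180.00 35.00
   5  6  7 2 120.00 35.00
   6  7  8 2 180.00 35.00
   4  9 10 2 180.00 35.00
   9 10 11 2 180.00 35.00
  10 11 12 2 180.00 35.00
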