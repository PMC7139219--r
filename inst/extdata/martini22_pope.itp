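; POPE template, Martini 2.2 dialect, with fragment-role annotations
[ moleculetype ]
; molname  nrexcl
POPE  1

[ atoms ]
;  id type resnr residue atom cgnr charge
   1 Qd    1 POPE  NH3     1   1.0000 ; role=headgroup
   2 Qa    1 POPE  PO4     2  -1.0000 ; role=phosphate
   3 Na    1 POPE  GL1     3   0.0000 ; role=glycerol
   4 Na    1 POPE  GL2     4   0.0000 ; role=glycerol
   5 C1    1 POPE  C1A     5   0.0000 ; role=tail sn-2 oleoyl
   6 C3    1 POPE  D2A     6   0.0000 ; role=tail sn-2 oleoyl cis bead
   7 C1    1 POPE  C3A     7   0.0000 ; role=tail sn-2 oleoyl
   8 C1    1 POPE  C4A     8   0.0000 ; role=tail sn-2 oleoyl
   9 C1    1 POPE  C1B     9   0.0000 ; role=tail sn-1 palmitoyl
  10 C1    1 POPE  C2B    10   0.0000 ; role=tail sn-1 palmitoyl
  11 C1    1 POPE  C3B    11   0.0000 ; role=tail sn-1 palmitoyl
  12 C1    1 POPE  C4B    12   0.0000 ; role=tail sn-1 palmitoyl

[ bonds ]
;  i  j funct length fc
   1  2 1 0.4700 1250.00
   2  3 1 0.4700 1250.00
   3  4 1 0.3700 1250.00
   3  5 1 0.4700 1250.00
   5  6 1 0.4700 1250.00
   6  7 1 0.4700 1250.00
   7  8 1 0.4700 1250.00
   4  9 1 0.4700 1250.00
   9 10 1 0.4700 1250.00
  10 11 1 0.4700 1250.00
  11 12 1 0.4700 1250.00

[ angles ]
;  i  j  k funct angle fc
   2  3  4 2 120.00 25.00
   2  3  5 2 180.00 25.00
   3  5  6 2 180.00 25.00
   5  6  7 2 120.00 45.00
   6  7  8 2 180.00 25.00
   4  9 10 2 180.00 25.00
   9 10 11 2 180.00 25.00
  10 11 12 2 180.00 25.00
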