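VV  sinexapt synthetic motif library
CC  Synthetic nucleotide count matrices in TRANSFAC flat format.
CC  The motif names follow the transcription factors classically reported at
CC  exapted SINE loci (POU/homeodomain factors and relatives); the counts
CC  are invented around field-standard consensus cores and are NOT the
CC  licensed TRANSFAC matrices.
//
ID  Oct-1
AC  SYN00001
NA  Oct-1
P0      A      C      G      T
01     16      2      1      1      A
02      1      2      1     16      T
03      1      2     16      1      G
04      2     16      1      1      C
05     16      2      1      1      A
06     16      2      1      1      A
07     16      2      1      1      A
08      1      2      1     16      T
XX
//
ID  Brn-2
AC  SYN00002
NA  Brn-2
P0      A      C      G      T
01     16      2      1      1      A
02      1      2      1     16      T
03      1      2     16      1      G
04      2     16      1      1      C
05     16      2      1      1      A
06      1      2      1     16      T
07     16      2      1      1      A
08     16      2      1      1      A
XX
//
ID  Cart-1
AC  SYN00003
NA  Cart-1
P0      A      C      G      T
01      2     16      1      1      C
02     16      2      1      1      A
03     16      2      1      1      A
04      1      2      1     16      T
05      1      2      1     16      T
06     16      2      1      1      A
07      5      5      5      5      N
08      1      2     16      1      G
XX
//
ID  Nkx6.1
AC  SYN00004
NA  Nkx6.1
P0      A      C      G      T
01      1      2      1     16      T
02      1      2      1     16      T
03     16      2      1      1      A
04     16      2      1      1      A
05      1      2      1     16      T
06      1      2      1     16      T
07     16      2      1      1      A
08      2     16      1      1      C
XX
//
ID  S8
AC  SYN00005
NA  S8
P0      A      C      G      T
01      1      2     16      1      G
02      1      2      1     16      T
03     16      2      1      1      A
04     16      2      1      1      A
05      1      2      1     16      T
06      1      2      1     16      T
07     16      2      1      1      A
08     16      2      1      1      A
XX
//
ID  SEF-1
AC  SYN00006
NA  SEF-1
P0      A      C      G      T
01     16      2      1      1      A
02      1      2      1     16      T
03      1      2      1     16      T
04      1      2      1     16      T
05      2     16      1      1      C
06      2     16      1      1      C
07      1      2      1     16      T
08      1      2     16      1      G
XX
//
ID  CDPCR3
AC  SYN00007
NA  CDPCR3
P0      A      C      G      T
01      2     16      1      1      C
02     16      2      1      1      A
03      1      2      1     16      T
04      2     16      1      1      C
05      1      2     16      1      G
06     16      2      1      1      A
07      1      2      1     16      T
08     16      2      1      1      A
XX
//
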