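AC  SYN001
XX
ID  V$EBOX_SYN
XX
P0      A      C      G      T
01      2     14      2      2
02     15      1      2      2
03      1     16      2      1
04      2      1     15      2
05      2      2      1     15
06      2      2     14      2
XX
//
AC  SYN002
XX
ID  V$GCBOX_SYN
XX
P0      A      C      G      T
01      1     10      8      1
02      0      2     18      0
03      1     15      3      1
04      0      3     16      1
05      2     13      3      2
06      1      2     16      1
07      1     14      4      1
08      0      4     15      1
//
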