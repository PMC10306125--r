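# lickbench stationary-bar pattern table, version 1
# 9 rows x 16 columns per pattern, 1 = LED on.
# The exact bar geometry on the panels is a package convention: analyses
# depend only on stimulus identity, never on this pixel art.
pattern: 0
1111111111111111
0000000000000000
0000000000000000
1111111111111111
0000000000000000
0000000000000000
1111111111111111
0000000000000000
0000000000000000
pattern: 45left
1001001001001001
0010010010010010
0100100100100100
1001001001001001
0010010010010010
0100100100100100
1001001001001001
0010010010010010
0100100100100100
pattern: 45right
1001001001001001
0100100100100100
0010010010010010
1001001001001001
0100100100100100
0010010010010010
1001001001001001
0100100100100100
0010010010010010
pattern: 90
1001001001001001
1001001001001001
1001001001001001
1001001001001001
1001001001001001
1001001001001001
1001001001001001
1001001001001001
1001001001001001
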