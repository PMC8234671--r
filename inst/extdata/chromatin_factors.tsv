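factor	expected_tier
POU5F2	high
ASH1L	high
BAZ2B	high
ATRX	high
SUV39H1	mid
EHMT2	mid
TRIM28	mid
DAXX	mid
SETDB1	none
CBX5	none
DNMT1	none
CHAF1A	none
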