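# Synthetic NBRE (NGFI-B response element) position frequency matrix.
# Counts constructed around the canonical consensus AAAGGTCA; this is a
# synthetic stand-in, not a database-derived matrix.
A	72	78	70	4	2	6	6	70
C	10	8	10	4	4	6	78	12
G	8	6	12	84	88	8	8	8
T	10	8	8	8	6	80	8	10
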