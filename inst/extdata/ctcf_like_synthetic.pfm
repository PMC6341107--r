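# Synthetic CTCF-like position frequency matrix (15 positions) with the
# asymmetric, orientation-bearing core CCACCAGGTGGCAGC. Synthetic stand-in
# for a database motif; supply your own PFM for real scans.
A	6	8	70	10	8	66	6	10	8	6	8	6	62	10	8
C	70	68	12	64	70	10	8	6	10	8	10	72	12	8	70
G	12	12	10	14	12	14	74	72	12	74	70	12	16	70	12
T	12	12	8	12	10	10	12	12	70	12	12	10	10	12	10
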