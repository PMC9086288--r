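REMARK   1 SYNTHETIC toy host-guest structure generated by the lvmetad package
REMARK   1 (not a deposited structure): three host pocket pseudo-atoms on
REMARK   1 chain A and a single-site ligand LIG on chain B, for exercising
REMARK   1 the COM/selection reader.
ATOM      1  C1  HST A   1       2.500   0.000   0.000  1.00  0.00           C
ATOM      2  O1  HST A   1       2.000   1.200   0.500  1.00  0.00           O
ATOM      3  N1  HST A   1       2.800  -1.000   0.800  1.00  0.00           N
HETATM    4  C1  LIG B   2       2.500   0.500   0.200  1.00  0.00           C
END
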