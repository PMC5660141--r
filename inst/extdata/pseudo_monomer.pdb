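REMARK   SYNTHETIC PSEUDO-MONOMER: five pseudo-atoms in an asymmetric
REMARK   arrangement around an actin-like radius, for helix building and
REMARK   density-synthesis tests. Not a real protein structure.
ATOM      1  CA  GLY A   1      25.000   0.000   0.000  1.00  0.00           C
ATOM      2  CA  GLY A   2      28.500   6.200   4.100  1.00  0.00           C
ATOM      3  CA  GLY A   3      21.300  -5.700   9.800  1.00  0.00           C
ATOM      4  CA  GLY A   4      30.100  -2.900  14.600  1.00  0.00           C
ATOM      5  CA  GLY A   5      18.900   8.400  19.700  1.00  0.00           C
END
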