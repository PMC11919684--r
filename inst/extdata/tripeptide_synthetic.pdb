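ATOM      1  N   MET A   1       1.621  -0.783  -0.600  1.00 90.00           N
ATOM      2  CA  MET A   1       2.300   0.000   0.000  1.00 90.00           C
ATOM      3  C   MET A   1       1.801   0.870   0.550  1.00 90.00           C
ATOM      4  O   MET A   1       2.728   1.673   0.850  1.00 90.00           O
ATOM      5  CB  MET A   1       3.582  -0.359  -0.300  1.00 90.00           C
ATOM      6  N   LYS A   2       0.490   1.732   0.900  1.00 80.00           N
ATOM      7  CA  LYS A   2      -0.399   2.265   1.500  1.00 80.00           C
ATOM      8  C   LYS A   2      -1.169   1.622   2.050  1.00 80.00           C
ATOM      9  O   LYS A   2      -2.121   2.396   2.350  1.00 80.00           O
ATOM     10  CB  LYS A   2      -0.268   3.590   1.200  1.00 80.00           C
ATOM     11  N   VAL A   3      -1.791   0.181   2.400  1.00 70.00           N
ATOM     12  CA  VAL A   3      -2.161  -0.787   3.000  1.00 70.00           C
ATOM     13  C   VAL A   3      -1.395  -1.433   3.550  1.00 70.00           C
ATOM     14  O   VAL A   3      -1.991  -2.505   3.850  1.00 70.00           O
ATOM     15  CB  VAL A   3      -3.489  -0.887   2.700  1.00 70.00           C
END
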