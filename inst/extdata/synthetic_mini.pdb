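HEADER    SYNTHETIC TEST STRUCTURE
TITLE     MINIMAL HAND-WRITTEN CA TRACE FOR PARSER TESTS (NOT A REAL PROTEIN)
ATOM      1  CA  GLY A  23       0.000   0.000   0.000  1.00  0.00           C
ATOM      2  CA  TRP A  24       3.800   0.000   0.000  1.00  0.00           C
ATOM      3  CA  ALA A  25       7.600   0.000   0.000  1.00  0.00           C
ATOM      4  CA  SER A  26      11.400   0.000   0.000  1.00  0.00           C
ATOM      5  CA  LYS A  27      15.200   0.000   0.000  1.00  0.00           C
ATOM      6  CA  PHE A  30      19.000   0.000   0.000  1.00  0.00           C
TER       7      PHE A  30
END
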