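ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00 94.41              
ATOM      2  CA  ALA A   2       1.704   1.798  -0.584  1.00 97.76              
ATOM      3  CA  ALA A   3      -0.748  -0.908   0.466  1.00 96.67              
ATOM      4  CA  ALA A   4       1.167  -1.001  -2.815  1.00 95.31              
ATOM      5  CA  ALA A   5      -1.338   0.653  -5.146  1.00 93.54              
ATOM      6  CA  ALA A   6      -1.663   3.850  -3.117  1.00 95.89              
ATOM      7  CA  ALA A   7      -2.360   4.132   0.608  1.00 93.81              
ATOM      8  CA  ALA A   8       0.730   4.565   2.776  1.00 96.99              
ATOM      9  CA  ALA A   9       4.203   3.161   2.138  1.00 96.15              
ATOM     10  CA  ALA A  10       1.727   0.643   3.541  1.00 95.23              
ATOM     11  CA  ALA A  11       0.401  -2.905   3.238  1.00 96.90              
ATOM     12  CA  ALA A  12       2.101  -4.357   0.165  1.00 93.24              
ATOM     13  CA  ALA A  13       4.005  -5.667   3.181  1.00 96.93              
ATOM     14  CA  ALA A  14       4.445  -2.111   4.445  1.00 97.01              
ATOM     15  CA  ALA A  15       3.111  -4.898   6.655  1.00 94.12              
ATOM     16  CA  ALA A  16       0.736  -6.811   4.387  1.00 93.91              
ATOM     17  CA  ALA A  17      -2.633  -5.963   2.847  1.00 95.45              
ATOM     18  CA  ALA A  18      -3.940  -3.239   0.542  1.00 94.81              
ATOM     19  CA  ALA A  19      -3.455  -0.319  -1.841  1.00 95.42              
ATOM     20  CA  ALA A  20      -4.320   1.029   1.605  1.00 95.06              
END   
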