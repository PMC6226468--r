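ATOM      1  N   CYS A   1       0.000   0.000   0.000  1.00  0.00
ATOM      2  CA  CYS A   1       1.458   0.000   0.000  1.00  0.00
ATOM      3  C   CYS A   1       2.005  -0.368   1.375  1.00  0.00
ATOM      4  O   CYS A   1       1.376  -0.095   2.397  1.00  0.00
ATOM      5  N   PRO A   2       3.179  -0.990   1.393  1.00  0.00
ATOM      6  CA  PRO A   2       3.812  -1.397   2.641  1.00  0.00
ATOM      7  C   PRO A   2       4.407  -0.197   3.369  1.00  0.00
ATOM      8  O   PRO A   2       4.822   0.778   2.742  1.00  0.00
ATOM      9  N   PRO A   3       4.446  -0.274   4.695  1.00  0.00
ATOM     10  CA  PRO A   3       4.990   0.805   5.510  1.00  0.00
ATOM     11  C   PRO A   3       6.514   0.828   5.440  1.00  0.00
ATOM     12  O   PRO A   3       7.152  -0.209   5.263  1.00  0.00
ATOM     13  N   PRO A   4       7.090   2.017   5.581  1.00  0.00
ATOM     14  CA  PRO A   4       8.538   2.177   5.535  1.00  0.00
ATOM     15  C   PRO A   4       9.185   1.682   6.824  1.00  0.00
ATOM     16  O   PRO A   4       8.580   1.739   7.894  1.00  0.00
ATOM     17  N   TRP A   5      10.417   1.197   6.714  1.00  0.00
ATOM     18  CA  TRP A   5      11.147   0.691   7.870  1.00  0.00
ATOM     19  C   TRP A   5      11.648   1.836   8.743  1.00  0.00
ATOM     20  O   TRP A   5      11.929   2.928   8.251  1.00  0.00
END
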