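ID SOX_ACAAAG_synthetic
P0 A C G T
01 97 1 1 1
02 1 97 1 1
03 97 1 1 1
04 97 1 1 1
05 97 1 1 1
06 1 1 97 1
//
ID SOX_ACAATG_synthetic
P0 A C G T
01 90 4 3 3
02 2 92 3 3
03 91 3 3 3
04 88 4 4 4
05 3 3 3 91
06 3 3 91 3
//
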