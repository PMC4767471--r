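case	sex	karyotype
1Dx	XX	25, X, +X, +21/50, idemx2
2Dx	XX	27, X, +X, +14, +18, +21
3R	XY	29, X, +X, +Y, +Y, +14, +18, +21/58, idemx2
4Dx	XX	26, X, +X, +14, +21
5Dx	XY	32, X, +1, +5, +6, +8, +10, +14, +19, +21, +22
6Dx	XX	34, X, +X, +1, +2, +6, +10, +11, +12, +14, +18, +21, +22
7Dx	XY	33, X, +Y, +1, +5, +6, +10, +11, +18, +19, +21, +22
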