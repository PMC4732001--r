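# Mean bond dissociation enthalpies, kJ/mol.
# Columns: element1 element2 order energy
# Orders: 1 single, 2 double, 3 triple. Aromatic bonds use the mean of the
# single and double entry for the pair (computed at load time).
# Pairs not listed fall back to 348 kJ/mol.
H  H  1 436
H  C  1 413
H  N  1 391
H  O  1 463
H  F  1 567
H  P  1 322
H  S  1 347
H  Cl 1 432
H  Br 1 366
H  I  1 299
C  C  1 348
C  C  2 614
C  C  3 839
C  N  1 293
C  N  2 615
C  N  3 891
C  O  1 358
C  O  2 743
C  F  1 485
C  P  1 264
C  S  1 259
C  S  2 573
C  Cl 1 328
C  Br 1 276
C  I  1 240
N  N  1 163
N  N  2 418
N  N  3 941
N  O  1 201
N  O  2 607
N  F  1 272
N  Cl 1 200
O  O  1 146
O  O  2 495
O  F  1 190
O  P  1 350
O  P  2 544
O  S  1 265
O  S  2 522
O  Cl 1 203
O  I  1 234
F  F  1 155
F  P  1 490
F  S  1 327
P  P  1 201
P  S  2 335
P  Cl 1 331
P  Br 1 272
S  S  1 266
S  S  2 425
S  Cl 1 253
S  Br 1 218
Cl Cl 1 242
Br Br 1 193
I  I  1 151
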