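# Reference structures for the built-in benchmark tasks.
# Structures drawn from the public records of the named drugs
# (stereochemistry omitted; similarity objectives use 2D fingerprints).
CC(C)(C(=O)O)c1ccc(cc1)C(O)CCCN2CCC(CC2)C(O)(c3ccccc3)c4ccccc4 fexofenadine
CCc1ccc(nc1)CCOc2ccc(cc2)CC3C(=O)NC(=O)S3 pioglitazone
COc1cc(N(C)CCN(C)C)c(NC(=O)C=C)cc1Nc2nccc(n2)c3cn(C)c4ccccc34 osimertinib
Cc1cccc(C)c1NC(=O)CN2CCN(CC2)CC(O)COc3ccccc3OC ranolazine
OC1(CN(C1)C(=O)c2ccc(F)c(F)c2Nc3ccc(I)cc3F)C4CCCCN4 cobimetinib
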