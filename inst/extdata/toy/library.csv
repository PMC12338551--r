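SMILES,Sample ID,Gene Symbol
CCO,C1,
CCCO,C2,SYGA
CCCCO,C3,
c1ccccc1O,C4,
c1ccccc1N.Cl,C5,
CC(=O)O,C6,SYGB
??notasmiles,C7,
CCS,C8,
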