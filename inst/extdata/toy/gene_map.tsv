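gene_symbol	uniprot_acc
SYGA	P00001
SYGB	P00002
SYGC	P00003
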