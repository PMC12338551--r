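cid,target_accession,target_taxon,activity_type,activity_value,activity_unit,target_gene_symbol
CID2,P00001,Homo sapiens,IC50,500,nM,SYGA
CID2,P00003,Homo sapiens,IC50,50,uM,SYGC
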