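molecule_chembl_id,target_accession,target_organism,target_type,assay_type,standard_type,pchembl_value,action_type,target_gene_symbol
CHEMBL1,P00001,Homo sapiens,SINGLE PROTEIN,B,IC50,7.1,INHIBITOR,SYGA
CHEMBL1,P00002,Homo sapiens,SINGLE PROTEIN,B,IC50,4.5,,SYGB
CHEMBL3,P00002,Homo sapiens,SINGLE PROTEIN,B,Ki,6.0,,SYGB
CHEMBL3,P00003,Homo sapiens,PROTEIN COMPLEX,B,IC50,6.5,,SYGC
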