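[
  {"ligand_id": "IUP1", "target_species": "Human", "affinity_parameter": "pKi",
   "affinity_value": "8.0", "action": "Antagonist",
   "target_uniprot": "P00001", "target_gene_symbol": "SYGA"},
  {"ligand_id": "IUP5", "target_species": "Human", "affinity_parameter": "pKi",
   "affinity_value": "7.0", "action": "Antagonist",
   "target_uniprot": "P00001", "target_gene_symbol": "SYGA"},
  {"ligand_id": "IUP5", "target_species": "Human", "affinity_parameter": "pKi",
   "affinity_value": "4.0", "action": "Antagonist",
   "target_uniprot": "P00002", "target_gene_symbol": "SYGB"},
  {"ligand_id": "IUP5", "target_species": "Mouse", "affinity_parameter": "pKi",
   "affinity_value": "8.0", "action": "Antagonist",
   "target_uniprot": "P00003", "target_gene_symbol": "SYGC"}
]
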