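inchikey	source	source_id
LFQSCWFLJHTTHZ-UHFFFAOYSA-N	chembl	CHEMBL1
LFQSCWFLJHTTHZ-UHFFFAOYSA-N	iuphar	IUP1
BDERNNFJNOPAEC-UHFFFAOYSA-N	pubchem	CID2
LRHPLDYGYMQRHN-UHFFFAOYSA-N	chembl	CHEMBL3
ISWSIDIOOBJBQZ-UHFFFAOYSA-N	drugbank	DB4
PAYRUJLWNCNPSJ-UHFFFAOYSA-N	iuphar	IUP5
QTBSBXVTEAMEQO-UHFFFAOYSA-N	pharmgkb	PA6
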