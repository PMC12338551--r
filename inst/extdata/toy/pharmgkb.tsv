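entity1_id	entity1_name	entity1_type	entity2_id	entity2_name	entity2_type
PA6	acetic acid	Chemical	PAGSYGC	SYGC	Gene
PA6	acetic acid	Chemical	PAGNOTAGENE	NOTAGENE	Gene
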