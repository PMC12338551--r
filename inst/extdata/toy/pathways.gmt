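SET1	toy calcium-signalling-like set	SYGA	SYGB
SET2	toy metabolism-like set	SYGB	SYGC
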