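gene_a	gene_b	evidence_type
RAP2B	RAP2C	co-localization; shared protein domains
BRAF	RHEB	same pathway; physical interaction
RALA	UBE2K	co-expression
KRAS	RASSF2	physical interaction
RGL2	KRAS	same pathway; physical interaction
RASSF2	APBB1IP	shared protein domains
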