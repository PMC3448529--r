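qualifier_id	strategy	value
APO:0000002	pato	PATO:0000460
APO:0000003	modifier	decreased-in-magnitude-relative-to
APO:0000004	modifier	increased-in-magnitude-relative-to
APO:0000005	pato	PATO:0000462
APO:0000250	pato	PATO:0000297
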